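SPECTRUM_CLASSES <- c("TG", "CA", "GG", "CC", "CT", "AG")

#' Count CpG mutation classes
#'
#' Over every \code{VARIABLE_CPG} site, each *distinct* non-CG state
#' observed at the site contributes one event: states differing from
#' CG at exactly one position are binned into the matching CG->XY
#' class (CG->TG, CG->CA, CG->GG, CG->CC, CG->CT, CG->AG); states
#' differing at both positions go to an explicit \code{other} bin.
#' Several taxa sharing the same derived state at a site count once;
#' with that convention a site carrying a single derived state
#' contributes exactly one event, so the class total equals the number
#' of variable CpG sites whenever no site has two independent derived
#' states.  CG is taken as ancestral wherever any taxon retains it; no
#' ancestral-state reconstruction is attempted.
#'
#' @param sc a \code{cpg_sites} object.
#' @return An object of class \code{cpg_spectrum}: list with
#'   \code{class_counts} (named integer vector over the six classes),
#'   \code{other}, \code{denominator} (number of CpG sites),
#'   \code{class_percents} (one decimal, half-up, of the denominator)
#'   and \code{n_variable_cpg}.
#' @export
count_classes <- function(sc) {
  stopifnot(inherits(sc, "cpg_sites"))
  var_states <- sc$states[sc$class == "VARIABLE_CPG", , drop = FALSE]
  counts <- stats::setNames(integer(length(SPECTRUM_CLASSES)),
                            SPECTRUM_CLASSES)
  other <- 0L
  if (nrow(var_states) > 0) {
    derived <- apply(var_states, 1, function(s) setdiff(unique(s), "CG"))
    derived <- unlist(derived, use.names = FALSE)
    one_step <- derived %in% SPECTRUM_CLASSES
    tab <- table(factor(derived[one_step], levels = SPECTRUM_CLASSES))
    counts[] <- as.integer(tab)
    other <- sum(!one_step)
  }
  names(counts) <- paste0("CG>", SPECTRUM_CLASSES)
  denom <- sc$counts$n_cpg_sites
  structure(list(
    class_counts = counts,
    other = other,
    denominator = denom,
    class_percents = if (denom > 0) round_half_up(100 * counts / denom, 1)
                     else counts * NA_real_,
    n_variable_cpg = sc$counts$n_variable_cpg
  ), class = "cpg_spectrum")
}

#' @export
print.cpg_spectrum <- function(x, ...) {
  cat("CpG mutation spectrum (denominator:", x$denominator, "CpG sites)\n")
  for (cl in names(x$class_counts))
    cat(sprintf("  %-6s %5d  (%.1f%%)\n", cl, x$class_counts[[cl]],
                x$class_percents[[cl]]))
  cat(sprintf("  other  %5d\n", x$other))
  invisible(x)
}

#' Per-taxon CpG->TpG/CpA perspective counts
#'
#' For each taxon, the number of variable CpG sites where that taxon
#' still carries CG while at least one other taxon carries TG or CA --
#' i.e. the deamination-transition events visible "from the
#' perspective" of a species that retains the CpG.
#'
#' @param sc a \code{cpg_sites} object.
#' @return named integer vector, one entry per taxon.
#' @export
perspective_counts <- function(sc) {
  stopifnot(inherits(sc, "cpg_sites"))
  var_states <- sc$states[sc$class == "VARIABLE_CPG", , drop = FALSE]
  out <- stats::setNames(integer(length(sc$taxa)), sc$taxa)
  if (nrow(var_states) == 0) return(out)
  has_tgca <- rowSums(var_states == "TG" | var_states == "CA") > 0
  for (k in seq_along(sc$taxa))
    out[k] <- sum(var_states[, k] == "CG" & has_tgca)
  out
}

#' Tabulate a spectrum for reporting
#'
#' @param ms a \code{cpg_spectrum} object.
#' @param path optional TSV path; when given the table is written
#'   there.
#' @return data.frame with columns \code{class}, \code{count},
#'   \code{percent} in a fixed order (six classes, then \code{other},
#'   then a \code{total_cpg_sites} denominator row).
#' @export
spectrum_report <- function(ms, path = NULL) {
  stopifnot(inherits(ms, "cpg_spectrum"))
  df <- data.frame(
    class = c(names(ms$class_counts), "other", "total_cpg_sites"),
    count = c(unname(ms$class_counts), ms$other, ms$denominator),
    percent = c(unname(ms$class_percents), NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
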