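SITE_CLASSES <- c("CONSISTENT_CPG", "VARIABLE_CPG", "NONCPG_VARIABLE",
                  "NONCPG_INVARIANT", "GAPPED")

#' Enumerate dinucleotide sites of an alignment
#'
#' In \code{nonoverlapping} mode the alignment is read in a fixed
#' dinucleotide frame anchored at the first column (start columns 1,
#' 3, 5, ...), so an alignment of \code{n_cols} columns yields
#' \code{floor(n_cols/2)} sites.  In \code{overlapping} mode every
#' adjacent column pair is a site (start columns 1 .. n_cols-1).
#'
#' @param aln a \code{cpg_aln} object.
#' @param frame_mode \code{"nonoverlapping"} (default) or
#'   \code{"overlapping"}.
#' @return list with \code{starts} (1-based first column of each site)
#'   and \code{states}, a character matrix (sites x taxa) of two-letter
#'   dinucleotide states.
#' @export
enumerate_sites <- function(aln,
                            frame_mode = c("nonoverlapping", "overlapping")) {
  stopifnot(inherits(aln, "cpg_aln"))
  frame_mode <- match.arg(frame_mode)
  if (aln$n_cols < 2)
    stop("alignment must have at least 2 columns")
  starts <- if (frame_mode == "nonoverlapping")
    seq.int(1L, 2L * (aln$n_cols %/% 2L) - 1L, by = 2L)
  else
    seq_len(aln$n_cols - 1L)
  m <- aln_matrix(aln)
  states <- vapply(aln$taxa,
                   function(tx) paste0(m[tx, starts], m[tx, starts + 1L]),
                   character(length(starts)))
  if (length(starts) == 1L)
    states <- matrix(states, nrow = 1, dimnames = list(NULL, aln$taxa))
  list(starts = starts, states = states)
}

#' Classify one dinucleotide site
#'
#' A site is \code{GAPPED} when any taxon's state contains a gap or an
#' N; otherwise \code{CONSISTENT_CPG} when every taxon is CG,
#' \code{VARIABLE_CPG} when at least one (but not all) is CG,
#' \code{NONCPG_VARIABLE} when no taxon is CG but states differ, and
#' \code{NONCPG_INVARIANT} otherwise.
#'
#' @param states character vector of two-letter per-taxon states.
#' @return one of the class labels above.
#' @export
classify_site <- function(states) {
  if (any(nchar(states) != 2))
    stop("dinucleotide states must have exactly 2 characters")
  if (any(grepl("[-N]", states))) return("GAPPED")
  is_cg <- states == "CG"
  if (all(is_cg)) return("CONSISTENT_CPG")
  if (any(is_cg)) return("VARIABLE_CPG")
  if (length(unique(states)) >= 2) return("NONCPG_VARIABLE")
  "NONCPG_INVARIANT"
}

#' Classify every dinucleotide site of an alignment
#'
#' Applies [classify_site()] over [enumerate_sites()] and aggregates
#' the counts used throughout the pipeline.  Columns carrying a gap or
#' N in any taxon are excluded both from the dinucleotide classes (as
#' \code{GAPPED}) and from the single-column SNP tally.
#'
#' @param aln a \code{cpg_aln} object.
#' @param frame_mode see [enumerate_sites()].
#' @return An object of class \code{cpg_sites}: list with
#'   \code{frame_mode}, \code{taxa}, \code{starts}, \code{states}
#'   (sites x taxa matrix), \code{class} (character vector per site)
#'   and \code{counts}, a list with \code{n_dinuc_sites},
#'   \code{n_cpg_sites}, \code{n_consistent_cpg}, \code{n_variable_cpg},
#'   \code{n_noncpg_variable}, \code{n_gapped},
#'   \code{n_noncpg_snp_columns}.
#' @export
classify_alignment <- function(aln,
                               frame_mode = c("nonoverlapping",
                                              "overlapping")) {
  frame_mode <- match.arg(frame_mode)
  es <- enumerate_sites(aln, frame_mode)
  states <- es$states
  n_sites <- nrow(states)

  gapped <- rowSums(matrix(grepl("[-N]", states), nrow = n_sites)) > 0
  is_cg <- states == "CG"
  n_cg <- rowSums(is_cg)
  n_taxa <- ncol(states)
  varies <- rowSums(states != states[, 1]) > 0

  cls <- character(n_sites)
  cls[gapped] <- "GAPPED"
  cls[!gapped & n_cg == n_taxa] <- "CONSISTENT_CPG"
  cls[!gapped & n_cg > 0 & n_cg < n_taxa] <- "VARIABLE_CPG"
  cls[!gapped & n_cg == 0 & varies] <- "NONCPG_VARIABLE"
  cls[!gapped & n_cg == 0 & !varies] <- "NONCPG_INVARIANT"

  # single columns variable outside all CpG-class sites
  m <- aln_matrix(aln)
  col_bad <- colSums(m == "-" | m == "N") > 0
  col_var <- colSums(m != rep(m[1, ], each = nrow(m))) > 0
  cpg_sites <- es$starts[cls %in% c("CONSISTENT_CPG", "VARIABLE_CPG")]
  in_cpg <- rep(FALSE, aln$n_cols)
  in_cpg[c(cpg_sites, cpg_sites + 1L)] <- TRUE
  n_snp_cols <- sum(col_var & !col_bad & !in_cpg)

  counts <- list(
    n_dinuc_sites = n_sites,
    n_cpg_sites = sum(cls %in% c("CONSISTENT_CPG", "VARIABLE_CPG")),
    n_consistent_cpg = sum(cls == "CONSISTENT_CPG"),
    n_variable_cpg = sum(cls == "VARIABLE_CPG"),
    n_noncpg_variable = sum(cls == "NONCPG_VARIABLE"),
    n_gapped = sum(cls == "GAPPED"),
    n_noncpg_snp_columns = n_snp_cols
  )
  structure(list(frame_mode = frame_mode, taxa = aln$taxa,
                 starts = es$starts, states = states, class = cls,
                 counts = counts),
            class = "cpg_sites")
}

#' @export
print.cpg_sites <- function(x, ...) {
  c <- x$counts
  cat("CpG site classification (", x$frame_mode, " frame)\n", sep = "")
  cat(sprintf("  dinucleotide sites : %d\n", c$n_dinuc_sites))
  cat(sprintf("  CpG sites          : %d (%d consistent, %d variable)\n",
              c$n_cpg_sites, c$n_consistent_cpg, c$n_variable_cpg))
  cat(sprintf("  non-CpG variable   : %d sites, %d SNP columns\n",
              c$n_noncpg_variable, c$n_noncpg_snp_columns))
  cat(sprintf("  gapped (excluded)  : %d\n", c$n_gapped))
  invisible(x)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Headline fractions from a site classification
#'
#' @param x a \code{cpg_sites} object, or a plain list of counts with
#'   at least \code{n_cpg_sites} and one of \code{n_variable_cpg} /
#'   \code{n_consistent_cpg} (and optionally \code{n_dinuc_sites},
#'   \code{n_noncpg_variable}).
#' @return list with \code{percent_cpg_altered} (full precision; NA
#'   when there are no CpG sites), \code{percent_cpg_altered_report}
#'   (rounded to the nearest integer), and, when the denominators are
#'   available, \code{percent_dinuc_cpg_variable} and
#'   \code{percent_dinuc_noncpg_variable} (one decimal, half-up).
#' @export
summarize_fractions <- function(x) {
  cnt <- if (inherits(x, "cpg_sites")) x$counts else x
  if (is.null(cnt$n_variable_cpg) && !is.null(cnt$n_consistent_cpg))
    cnt$n_variable_cpg <- cnt$n_cpg_sites - cnt$n_consistent_cpg
  stopifnot(!is.null(cnt$n_cpg_sites), !is.null(cnt$n_variable_cpg))
  out <- list()
  if (cnt$n_cpg_sites == 0) {
    out$percent_cpg_altered <- NA_real_
    out$percent_cpg_altered_report <- NA_real_
  } else {
    out$percent_cpg_altered <- 100 * cnt$n_variable_cpg / cnt$n_cpg_sites
    out$percent_cpg_altered_report <- round_half_up(out$percent_cpg_altered)
  }
  if (!is.null(cnt$n_dinuc_sites) && cnt$n_dinuc_sites > 0) {
    out$percent_dinuc_cpg_variable <-
      round_half_up(100 * cnt$n_variable_cpg / cnt$n_dinuc_sites, 1)
    if (!is.null(cnt$n_noncpg_variable))
      out$percent_dinuc_noncpg_variable <-
        round_half_up(100 * cnt$n_noncpg_variable / cnt$n_dinuc_sites, 1)
  }
  out
}

#' Write the per-site classification as TSV
#'
#' Columns: \code{start} (0-based aligned column of the site's first
#' residue, matching the BED-like region-map convention), \code{end}
#' (half-open), \code{class}, then one state column per taxon.  When a
#' region map is supplied each site is annotated with the island it
#' falls in.
#'
#' @param sc a \code{cpg_sites} object.
#' @param path output TSV path.
#' @param region_map optional data.frame from [read_region_map()].
#' @return \code{path}, invisibly.
#' @export
write_site_report <- function(sc, path, region_map = NULL) {
  stopifnot(inherits(sc, "cpg_sites"))
  df <- data.frame(start = sc$starts - 1L, end = sc$starts + 1L,
                   class = sc$class, stringsAsFactors = FALSE)
  st <- as.data.frame(sc$states, stringsAsFactors = FALSE)
  names(st) <- sc$taxa
  df <- cbind(df, st)
  if (!is.null(region_map)) {
    idx <- findInterval(df$start, region_map$start)
    island <- rep(NA_character_, nrow(df))
    ok <- idx >= 1
    ok[ok] <- df$start[ok] < region_map$end[idx[ok]]
    island[ok] <- region_map$name[idx[ok]]
    df$island <- island
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
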