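#' Run the full phylo-epigenetic analysis
#'
#' classify -> spectrum -> recode -> trees -> calibrate -> compare, with
#' every product written to \code{out_dir}: per-site classification
#' (\code{sites.tsv}), spectrum table (\code{spectrum.tsv}), percent
#' identity matrix (\code{identity.tsv}), p-distance matrix
#' (\code{distance.tsv}), recoded FASTA + column map
#' (\code{recoded.fasta}, \code{recoded.fasta.map.tsv}), genetic and
#' phylo-epigenetic Newick trees (\code{tree_genetic.nwk},
#' \code{tree_epigenetic.nwk}, plus \code{*_calibrated.nwk} when a
#' calibration is given) and a versioned JSON summary
#' (\code{summary.json}).  Everything is computed before anything is
#' written, so a failing stage leaves no partial output behind.  The
#' run is deterministic: identical inputs give byte-identical outputs.
#'
#' The run aborts if the spectrum total (class counts plus the
#' \code{other} bin) falls below the number of variable CpG sites,
#' which would mean a variable site contributed no event.
#'
#' @param aln path to an aligned multi-FASTA, or a \code{cpg_aln}.
#' @param out_dir output directory (created if needed).
#' @param frame_mode see [enumerate_sites()].
#' @param count_gaps see [p_distance()] (full alignment only).
#' @param calibration optional list \code{(taxon_a, taxon_b, age)}.
#' @param keep_invariant see [recode_alignment()].
#' @param region_map optional region-map path (see
#'   [read_region_map()]) used to annotate the site report.
#' @return the summary list (also written as \code{summary.json}),
#'   invisibly.
#' @export
run_all <- function(aln, out_dir,
                    frame_mode = c("nonoverlapping", "overlapping"),
                    count_gaps = FALSE, calibration = NULL,
                    keep_invariant = TRUE, region_map = NULL) {
  frame_mode <- match.arg(frame_mode)
  if (is.character(aln)) aln <- read_alignment(aln)
  stopifnot(inherits(aln, "cpg_aln"))
  rm <- if (!is.null(region_map)) read_region_map(region_map, aln$n_cols)

  sc <- classify_alignment(aln, frame_mode)
  ms <- count_classes(sc)
  if (sum(ms$class_counts) + ms$other < ms$n_variable_cpg)
    stop("spectrum accounting error: fewer events than variable CpG sites")
  persp <- perspective_counts(sc)
  ra <- recode_alignment(sc, keep_invariant = keep_invariant)
  ident <- percent_identity(aln, count_gaps = count_gaps)
  pdist <- p_distance(aln, count_gaps = count_gaps)
  trees <- build_both_trees(aln, sc, calibration = NULL,
                            count_gaps = count_gaps,
                            keep_invariant = keep_invariant)
  cal_trees <- if (!is.null(calibration)) {
    list(genetic = calibrate(trees$genetic, calibration$taxon_a,
                             calibration$taxon_b, calibration$age),
         epigenetic = calibrate(trees$epigenetic, calibration$taxon_a,
                                calibration$taxon_b, calibration$age))
  }
  fr <- summarize_fractions(sc)
  summary <- list(
    schema_version = 1,
    n_taxa = length(aln$taxa),
    n_cols = aln$n_cols,
    frame_mode = frame_mode,
    counts = sc$counts,
    fractions = fr,
    spectrum = list(class_counts = as.list(ms$class_counts),
                    class_percents = as.list(ms$class_percents),
                    other = ms$other,
                    denominator = ms$denominator),
    perspective_counts = as.list(persp),
    rf_genetic_vs_epigenetic = rf_distance(trees$genetic,
                                           trees$epigenetic),
    calibration = if (!is.null(calibration))
      list(taxon_a = calibration$taxon_a, taxon_b = calibration$taxon_b,
           age = calibration$age)
  )

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_site_report(sc, fp("sites.tsv"), region_map = rm)
  spectrum_report(ms, fp("spectrum.tsv"))
  utils::write.table(ident, fp("identity.tsv"), sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(pdist, fp("distance.tsv"), sep = "\t", quote = FALSE,
                     col.names = NA)
  write_recoded_fasta(ra, fp("recoded.fasta"))
  write_newick(trees$genetic, fp("tree_genetic.nwk"))
  write_newick(trees$epigenetic, fp("tree_epigenetic.nwk"))
  if (!is.null(cal_trees)) {
    write_newick(cal_trees$genetic, fp("tree_genetic_calibrated.nwk"))
    write_newick(cal_trees$epigenetic, fp("tree_epigenetic_calibrated.nwk"))
  }
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(summary)
}
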