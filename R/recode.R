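#' Recode CpG-class sites to a binary A/T matrix
#'
#' One recoded column is emitted per gap-free CpG-class site
#' (CONSISTENT_CPG or VARIABLE_CPG).  A taxon gets \code{A} when its
#' own state at the site is CG and \code{T} when it lacks the CG at a
#' site where at least one taxon has it.  Non-CpG and gapped sites
#' emit no column.  Consistent sites therefore become invariant
#' all-\code{A} columns; they carry no topological signal but dilute
#' p-distances, which matters for branch-length scale, and are kept by
#' default.
#'
#' @param sc a \code{cpg_sites} object.
#' @param keep_invariant keep the all-A columns from consistent CpG
#'   sites (default TRUE)?
#' @return An object of class \code{cpg_recoded}: list with
#'   \code{taxa}, \code{chars} (named character vector of A/T strings),
#'   \code{site_index} (1-based aligned start column per recoded
#'   column) and \code{n_sites}.
#' @export
recode_alignment <- function(sc, keep_invariant = TRUE) {
  stopifnot(inherits(sc, "cpg_sites"))
  keep <- if (keep_invariant) c("CONSISTENT_CPG", "VARIABLE_CPG")
          else "VARIABLE_CPG"
  sel <- sc$class %in% keep
  states <- sc$states[sel, , drop = FALSE]
  bin <- ifelse(states == "CG", "A", "T")
  chars <- apply(bin, 2, paste, collapse = "")
  if (nrow(states) == 0) chars <- stats::setNames(rep("", ncol(states)),
                                                  sc$taxa)
  names(chars) <- sc$taxa
  structure(list(taxa = sc$taxa, chars = chars,
                 site_index = sc$starts[sel], n_sites = sum(sel)),
            class = "cpg_recoded")
}

#' @export
print.cpg_recoded <- function(x, ...) {
  cat("A/T recoded alignment:", length(x$taxa), "taxa x", x$n_sites,
      "CpG-class sites\n")
  invisible(x)
}

#' Recoded matrix as a character matrix
#'
#' @param ra a \code{cpg_recoded} object.
#' @return character matrix (taxa x recoded columns) over \{A,T\}.
#' @export
recoded_matrix <- function(ra) {
  stopifnot(inherits(ra, "cpg_recoded"))
  if (ra$n_sites == 0)
    return(matrix(character(0), nrow = length(ra$taxa), ncol = 0,
                  dimnames = list(ra$taxa, NULL)))
  m <- matrix(unlist(strsplit(ra$chars, ""), use.names = FALSE),
              nrow = length(ra$taxa), byrow = TRUE)
  rownames(m) <- ra$taxa
  m
}

#' Write a recoded matrix to FASTA plus a column-map sidecar
#'
#' The sidecar TSV maps each recoded column to the aligned columns it
#' came from, using 0-based half-open coordinates: columns
#' \code{recoded_col}, \code{aligned_start}, \code{aligned_end}.
#'
#' @param ra a \code{cpg_recoded} object.
#' @param path output FASTA path.
#' @param map_path sidecar path (default \code{<path>.map.tsv}).
#' @return \code{path}, invisibly.
#' @export
write_recoded_fasta <- function(ra, path,
                                map_path = paste0(path, ".map.tsv")) {
  stopifnot(inherits(ra, "cpg_recoded"))
  write_alignment(ra, path)
  map <- data.frame(recoded_col = seq_len(ra$n_sites) - 1L,
                    aligned_start = ra$site_index - 1L,
                    aligned_end = ra$site_index + 1L)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a recoded matrix written by [write_recoded_fasta()]
#'
#' @param path FASTA path.
#' @param map_path sidecar path (default \code{<path>.map.tsv}).
#' @return a \code{cpg_recoded} object.
#' @export
read_recoded_fasta <- function(path, map_path = paste0(path, ".map.tsv")) {
  recs <- Biostrings::readBStringSet(path)
  map <- utils::read.table(map_path, sep = "\t", header = TRUE)
  chars <- stats::setNames(as.character(recs), sub("\\s.*$", "", names(recs)))
  structure(list(taxa = names(chars), chars = chars,
                 site_index = map$aligned_start + 1L,
                 n_sites = nrow(map)),
            class = "cpg_recoded")
}
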