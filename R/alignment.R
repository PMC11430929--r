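#' Construct a multiple alignment object
#'
#' Container for an aligned set of sequences over the alphabet
#' \code{A,C,G,T,N,-}.  Rows are uppercased and \code{U} is mapped to
#' \code{T}; any other character outside the alphabet is mapped to
#' \code{N} with a warning.  The gap character is \code{-} only; a
#' \code{.} anywhere in a row is an error.
#'
#' @param taxa character vector of unique, non-empty taxon labels.
#' @param rows character vector of aligned sequences, one per taxon,
#'   all of the same length (>= 2 columns).
#' @return An object of class \code{cpg_aln}: a list with elements
#'   \code{taxa}, \code{seqs} (named character vector) and
#'   \code{n_cols}.
#' @export
new_alignment <- function(taxa, rows) {
  taxa <- as.character(taxa)
  rows <- as.character(rows)
  if (length(taxa) != length(rows))
    stop("taxa and rows must have the same length")
  if (length(taxa) < 2)
    stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (any(!nzchar(taxa)))
    stop("empty taxon label")
  if (any(grepl(".", rows, fixed = TRUE)))
    stop("'.' found in sequence: only '-' is accepted as the gap character")
  rows <- toupper(rows)
  rows <- gsub("U", "T", rows, fixed = TRUE)
  bad <- gsub("[ACGTN-]", "", rows)
  if (any(nzchar(bad))) {
    chars <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    warning("characters outside {A,C,G,T,N,-} mapped to N: ",
            paste(chars, collapse = " "))
    rows <- gsub("[^ACGTN-]", "N", rows)
  }
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("not an alignment: rows have unequal lengths (",
         paste(range(lens), collapse = "-"), ")")
  if (lens[1] < 2)
    stop("alignment must have at least 2 columns")
  names(rows) <- taxa
  structure(list(taxa = taxa, seqs = rows, n_cols = unname(lens[1])),
            class = "cpg_aln")
}

#' Read an aligned multi-FASTA file
#'
#' @param path path to a multi-FASTA file with >= 2 records of equal
#'   length.
#' @return A \code{cpg_aln} object; see [new_alignment()] for the
#'   normalisation applied to residues.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0)
    stop("empty FASTA file: ", path)
  if (length(recs) < 2)
    stop("an alignment needs at least 2 records, found ", length(recs))
  labels <- sub("\\s.*$", "", names(recs))
  new_alignment(labels, as.character(recs))
}

#' Write an alignment (or recoded matrix) to multi-FASTA
#'
#' @param x a \code{cpg_aln} or \code{cpg_recoded} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(x, path) {
  seqs <- if (inherits(x, "cpg_recoded")) x$chars else x$seqs
  set <- Biostrings::BStringSet(seqs)
  names(set) <- if (inherits(x, "cpg_recoded")) x$taxa else x$taxa
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Alignment as a character matrix
#'
#' @param aln a \code{cpg_aln} object.
#' @return character matrix, taxa in rows, aligned columns in columns.
#' @export
aln_matrix <- function(aln) {
  stopifnot(inherits(aln, "cpg_aln"))
  m <- matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
              nrow = length(aln$taxa), ncol = aln$n_cols, byrow = TRUE)
  rownames(m) <- aln$taxa
  m
}

#' @export
print.cpg_aln <- function(x, ...) {
  cat("Multiple alignment:", length(x$taxa), "taxa x", x$n_cols, "columns\n")
  show <- substr(x$seqs, 1, 60)
  for (i in seq_along(x$taxa))
    cat(sprintf("  %-15s %s%s\n", x$taxa[i], show[i],
                if (x$n_cols > 60) "..." else ""))
  invisible(x)
}

#' Read a BED-like region map
#'
#' Three-column TSV (island name, aligned start, aligned end) using
#' 0-based half-open column intervals, as in BED.  Intervals must be
#' sorted, non-overlapping, within the alignment, and names unique.
#'
#' @param path path to the TSV file (no header).
#' @param n_cols alignment width the intervals must fit in.
#' @return data.frame with columns \code{name}, \code{start},
#'   \code{end} (0-based half-open, as read).
#' @export
read_region_map <- function(path, n_cols) {
  if (!file.exists(path))
    stop("region map not found: ", path)
  rm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  if (anyDuplicated(rm$name))
    stop("duplicate island names in region map")
  if (any(rm$start < 0) || any(rm$end > n_cols))
    stop("region map interval outside [0, n_cols)")
  if (any(rm$end <= rm$start))
    stop("empty or inverted interval in region map")
  if (is.unsorted(rm$start, strictly = TRUE))
    stop("region map intervals must be sorted by start")
  if (any(rm$start[-1] < rm$end[-nrow(rm)]))
    stop("region map intervals overlap")
  rm
}
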