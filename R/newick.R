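#' Read a Newick tree
#'
#' Trees are held as \pkg{ape} \code{phylo} objects throughout.  After
#' parsing, root-to-tip path lengths are inspected: when they are all
#' equal (within \code{tol}) the tree is flagged ultrametric and node
#' heights are derivable via [node_heights()].
#'
#' @param path path to a Newick file, or a literal Newick string
#'   (anything containing \code{"("}).
#' @param tol tolerance on root-to-tip path equality.
#' @return a \code{phylo} object with attribute \code{ultrametric}
#'   (logical).
#' @export
read_newick <- function(path, tol = 1e-8) {
  tr <- if (grepl("(", path, fixed = TRUE))
    ape::read.tree(text = path)
  else {
    if (!file.exists(path)) stop("tree file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tr))
    stop("Newick parse error in: ", path)
  attr(tr, "ultrametric") <-
    !is.null(tr$edge.length) && ape::is.ultrametric(tr, tol = tol)
  tr
}

#' Write a tree to Newick
#'
#' Branch lengths are printed with full precision (>= 6 significant
#' digits).  A negative branch length is an error: it would mean a
#' child sitting above its parent, which violates ultrametricity.
#'
#' @param tree a \code{phylo} object with edge lengths.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length: ultrametric violation")
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Node heights of an ultrametric tree
#'
#' Heights are measured from the leaves (all at height 0) up to the
#' root.  For a non-ultrametric tree the height of a node is the
#' maximum root-to-tip depth minus the node's depth, which only has the
#' usual meaning when the tree is clock-like.
#'
#' @param tree a \code{phylo} object with edge lengths.
#' @return named numeric vector over all nodes (tips first, then
#'   internal nodes in ape numbering); names are tip labels for tips
#'   and node numbers for internal nodes.
#' @export
node_heights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  names(h) <- c(tree$tip.label,
                as.character(ape::Ntip(tree) + seq_len(tree$Nnode)))
  h
}

#' Height of the most recent common ancestor of two taxa
#'
#' @param tree an ultrametric \code{phylo} object.
#' @param taxon_a,taxon_b tip labels.
#' @return the MRCA's height above the leaves.
#' @export
mrca_height <- function(tree, taxon_a, taxon_b) {
  missing <- setdiff(c(taxon_a, taxon_b), tree$tip.label)
  if (length(missing))
    stop("taxon not in tree: ", paste(missing, collapse = ", "))
  node <- ape::getMRCA(tree, c(taxon_a, taxon_b))
  unname(node_heights(tree)[as.character(node)])
}
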