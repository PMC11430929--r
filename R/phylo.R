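as_char_matrix <- function(x) {
  if (inherits(x, "cpg_aln")) return(aln_matrix(x))
  if (inherits(x, "cpg_recoded")) return(recoded_matrix(x))
  if (is.matrix(x) && is.character(x)) return(x)
  stop("expected a cpg_aln, cpg_recoded or character matrix")
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing residues over comparable columns.  By
#' default a column is comparable for a pair when neither row carries
#' a gap or N there.  With \code{count_gaps = TRUE}, gap-versus-residue
#' columns are additionally counted as comparable differences
#' (gap-gap and any N are still excluded).
#'
#' @param x a \code{cpg_aln}, \code{cpg_recoded} or character matrix
#'   (taxa in rows).
#' @param count_gaps score gap/residue columns as differences?
#' @return symmetric numeric matrix with zero diagonal and taxa as
#'   dimnames.
#' @export
p_distance <- function(x, count_gaps = FALSE) {
  m <- as_char_matrix(x)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  taxa <- rownames(m)
  gap <- m == "-"
  bad <- m == "N"
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (count_gaps) {
        comp <- !(bad[i, ] | bad[j, ]) & !(gap[i, ] & gap[j, ])
      } else {
        comp <- !(bad[i, ] | bad[j, ] | gap[i, ] | gap[j, ])
      }
      nc <- sum(comp)
      if (nc == 0)
        stop("no comparable columns between ", taxa[i], " and ", taxa[j])
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Percent identity matrix
#'
#' 100 x identical / comparable columns per pair, rounded to two
#' decimals, diagonal 100: the similarity counterpart of
#' [p_distance()] as produced by standard alignment viewers.
#'
#' @inheritParams p_distance
#' @return symmetric numeric matrix (percent), diagonal 100.
#' @export
percent_identity <- function(x, count_gaps = FALSE) {
  d <- p_distance(x, count_gaps = count_gaps)
  round(100 * (1 - d), 2)
}

#' UPGMA clustering of a distance matrix
#'
#' From-scratch unweighted pair group method with arithmetic mean:
#' repeatedly merge the pair of clusters at minimal distance, place
#' the new node at half that distance, and update distances to the
#' merged cluster as the size-weighted arithmetic mean (UPGMA proper,
#' not WPGMA).  Among equal-minimum pairs the lexicographically
#' smallest pair of cluster creation indices is merged, so the result
#' is deterministic across platforms; with all pairwise distances
#' distinct the topology is exactly invariant to input order.
#'
#' @param dm symmetric numeric matrix with zero diagonal, taxa as
#'   dimnames, no NaN and no negative entries.
#' @return an ultrametric \code{phylo} object.
#' @export
upgma <- function(dm) {
  if (!is.matrix(dm) || is.null(rownames(dm)))
    stop("dm must be a matrix with taxa as dimnames")
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 taxa")
  if (any(!is.finite(dm)) || any(dm < 0))
    stop("distance matrix has NaN, infinite or negative entries")
  if (max(abs(dm - t(dm))) > 1e-12)
    stop("distance matrix is not symmetric")
  taxa <- rownames(dm)

  # active clusters keyed by creation index: 1..n are leaves
  D <- dm
  key <- seq_len(n)              # creation index of each active cluster
  size <- rep(1L, n)
  height <- rep(0, n)
  frag <- taxa                   # newick fragment per active cluster
  next_key <- n + 1L

  while (length(key) > 1) {
    k <- length(key)
    dmin <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (D[i, j] < dmin - 1e-15) { dmin <- D[i, j]; bi <- i; bj <- j }
      }
    }
    h <- dmin / 2
    newfrag <- sprintf("(%s:%s,%s:%s)",
                       frag[bi], format(h - height[bi], digits = 12),
                       frag[bj], format(h - height[bj], digits = 12))
    newrow <- (size[bi] * D[bi, ] + size[bj] * D[bj, ]) /
      (size[bi] + size[bj])
    keep <- setdiff(seq_len(k), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    frag <- c(frag[keep], newfrag)
    height <- c(height[keep], h)
    size <- c(size[keep], size[bi] + size[bj])
    key <- c(key[keep], next_key)
    next_key <- next_key + 1L
  }
  tr <- ape::read.tree(text = paste0(frag, ";"))
  attr(tr, "ultrametric") <- TRUE
  tr
}

#' Calibrate an ultrametric tree at a named divergence
#'
#' Every node height is multiplied by \code{age / h}, where \code{h}
#' is the current height of the most recent common ancestor of the
#' two named taxa; afterwards that node sits exactly at \code{age}.
#' Topology and all height ratios are preserved.
#'
#' @param tree an ultrametric \code{phylo} object.
#' @param taxon_a,taxon_b tip labels of the calibration pair.
#' @param age known divergence age (> 0), e.g. in My.
#' @return the rescaled \code{phylo} object.
#' @export
calibrate <- function(tree, taxon_a, taxon_b, age) {
  stopifnot(inherits(tree, "phylo"), age > 0)
  depth <- ape::node.depth.edgelength(tree)
  tips <- depth[seq_len(ape::Ntip(tree))]
  if (max(tips) - min(tips) > 1e-6 * max(1, max(tips)))
    stop("calibration requires an ultrametric tree")
  h <- mrca_height(tree, taxon_a, taxon_b)
  if (h <= 0)
    stop("zero-height calibration node: ", taxon_a, "/", taxon_b,
         " have no divergence to rescale")
  tree$edge.length <- tree$edge.length * (age / h)
  attr(tree, "ultrametric") <- TRUE
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartitions of the two
#' (unrooted) trees; 0 means identical unrooted topology.
#'
#' @param t1,t2 \code{phylo} objects over the same leaf set.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ between the two trees")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Build the genetic and the phylo-epigenetic tree
#'
#' The genetic tree is the UPGMA tree of p-distances over the full
#' alignment; the phylo-epigenetic tree is the UPGMA tree of
#' p-distances over the binary A/T recoded matrix of CpG-class sites.
#' When all sequences are identical both collapse to zero-height
#' degenerate trees.
#'
#' @param aln a \code{cpg_aln} object.
#' @param sc the matching \code{cpg_sites} classification.
#' @param calibration optional list \code{(taxon_a, taxon_b, age)}
#'   applied to both trees.
#' @param count_gaps passed to [p_distance()] for the full alignment.
#' @param keep_invariant passed to [recode_alignment()].
#' @return list with elements \code{genetic} and \code{epigenetic}
#'   (\code{phylo} objects).
#' @export
build_both_trees <- function(aln, sc, calibration = NULL,
                             count_gaps = FALSE, keep_invariant = TRUE) {
  stopifnot(inherits(aln, "cpg_aln"), inherits(sc, "cpg_sites"))
  ra <- recode_alignment(sc, keep_invariant = keep_invariant)
  if (ra$n_sites == 0)
    stop("no CpG-class sites: cannot build the phylo-epigenetic tree")
  tg <- upgma(p_distance(aln, count_gaps = count_gaps))
  te <- upgma(p_distance(ra))
  if (!is.null(calibration)) {
    tg <- calibrate(tg, calibration$taxon_a, calibration$taxon_b,
                    calibration$age)
    te <- calibrate(te, calibration$taxon_a, calibration$taxon_b,
                    calibration$age)
  }
  list(genetic = tg, epigenetic = te)
}
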