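# shared fixtures and independent oracles

make_aln <- function(rows, taxa = LETTERS[seq_along(rows)]) {
  new_alignment(taxa, rows)
}

# random ACGT alignment; cg_rich raises the chance of CG dinucleotides
random_alignment <- function(n_taxa, n_cols, seed, cg_rich = FALSE) {
  set.seed(seed)
  p <- if (cg_rich) c(0.15, 0.35, 0.35, 0.15) else rep(0.25, 4)
  rows <- vapply(seq_len(n_taxa), function(i)
    paste(sample(c("A", "C", "G", "T"), n_cols, replace = TRUE, prob = p),
          collapse = ""), character(1))
  new_alignment(paste0("t", seq_len(n_taxa)), rows)
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  d
}

# brute-force UPGMA oracle: at every step the distance between two
# clusters is recomputed as the flat mean over all leaf pairs in the
# ORIGINAL matrix (no incremental update), which is the defining
# property of UPGMA proper
upgma_oracle <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  height <- rep(0, n)
  frag <- rownames(dm)
  while (length(clusters) > 1) {
    k <- length(clusters)
    dmin <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dd <- mean(dm[clusters[[i]], clusters[[j]]])
        if (dd < dmin - 1e-15) { dmin <- dd; bi <- i; bj <- j }
      }
    }
    h <- dmin / 2
    newfrag <- sprintf("(%s:%s,%s:%s)",
                       frag[bi], format(h - height[bi], digits = 12),
                       frag[bj], format(h - height[bj], digits = 12))
    keep <- setdiff(seq_len(k), c(bi, bj))
    clusters <- c(clusters[keep], list(c(clusters[[bi]], clusters[[bj]])))
    frag <- c(frag[keep], newfrag)
    height <- c(height[keep], h)
  }
  ape::read.tree(text = paste0(frag, ";"))
}

expect_same_ultrametric_tree <- function(t1, t2, tol = 1e-9) {
  expect_equal(rf_distance(t1, t2), 0)
  h1 <- sort(node_heights(t1))
  h2 <- sort(node_heights(t2))
  expect_equal(unname(h1), unname(h2), tolerance = tol)
}

# root-to-leaf height spread of a tree (0 for an ultrametric tree)
height_spread <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  tips <- depth[seq_len(ape::Ntip(tree))]
  max(tips) - min(tips)
}
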