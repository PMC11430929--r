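test_that("p-distance counts mismatches over comparable columns", {
  expect_equal(unname(p_distance(make_aln(c("ACGT", "ACGT")))[1, 2]), 0)
  expect_equal(unname(p_distance(make_aln(c("ACGT", "ACTT")))[1, 2]), 0.25)
  # gap column excluded by default
  expect_equal(unname(p_distance(make_aln(c("AC-T", "ACGT")))[1, 2]), 0)
  # with count_gaps a gap/residue column is a comparable difference
  expect_equal(unname(p_distance(make_aln(c("AC-T", "ACGT")),
                                 count_gaps = TRUE)[1, 2]), 0.25)
  # no comparable columns at all is an error naming the pair
  expect_error(p_distance(make_aln(c("NN", "AC"))), "A and B")
})

test_that("percent identity mirrors p-distance as a similarity", {
  aln <- make_aln(c("ACGT", "ACTT", "ACGT"))
  id <- percent_identity(aln)
  expect_equal(unname(diag(id)), c(100, 100, 100))
  expect_equal(unname(id[1, 2]), 75.00)
  expect_equal(unname(id[1, 3]), 100.00)
  expect_true(isSymmetric(id))
})

test_that("UPGMA reproduces the worked three-taxon example", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(mrca_height(tr, "A", "B"), 1)
  expect_equal(mrca_height(tr, "A", "C"), 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_same_ultrametric_tree(read_newick(f),
                               read_newick("((A:1,B:1):1,C:2);"))
})

test_that("two-taxon UPGMA puts the root at half the distance", {
  d <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(mrca_height(upgma(d), "A", "B"), 0.25)
})

test_that("UPGMA rejects invalid distance matrices", {
  d <- random_distance_matrix(3, seed = 1)
  d_neg <- d; d_neg[1, 2] <- d_neg[2, 1] <- -0.1
  expect_error(upgma(d_neg), "negative")
  d_nan <- d; d_nan[1, 2] <- d_nan[2, 1] <- NaN
  expect_error(upgma(d_nan), "NaN")
  d_asym <- d; d_asym[1, 2] <- d_asym[1, 2] + 1
  expect_error(upgma(d_asym), "symmetric")
})

test_that("UPGMA equals the brute-force re-averaging oracle", {
  for (seed in 1:20) {
    n <- sample(4:8, 1)
    d <- random_distance_matrix(n, seed = 3000 + seed)
    expect_same_ultrametric_tree(upgma(d), upgma_oracle(d))
  }
})

test_that("UPGMA output is ultrametric and order-invariant", {
  for (seed in 31:40) {
    d <- random_distance_matrix(6, seed = seed)
    tr <- upgma(d)
    expect_lt(height_spread(tr), 1e-9)
    perm <- sample(6)
    tr2 <- upgma(d[perm, perm])
    expect_same_ultrametric_tree(tr, tr2)
  }
})

test_that("calibration rescales heights exactly and preserves ratios", {
  d <- random_distance_matrix(5, seed = 77)
  tr <- upgma(d)
  h_ab <- mrca_height(tr, "t1", "t2")
  cal <- calibrate(tr, "t1", "t2", 1.7)
  expect_equal(mrca_height(cal, "t1", "t2"), 1.7, tolerance = 1e-12)
  expect_equal(rf_distance(tr, cal), 0)
  # all height ratios preserved: heights scale by one factor
  expect_equal(unname(sort(node_heights(cal))),
               unname(sort(node_heights(tr))) * (1.7 / h_ab),
               tolerance = 1e-12)
  # recalibrating with the same spec is the identity
  cal2 <- calibrate(cal, "t1", "t2", 1.7)
  expect_equal(cal2$edge.length, cal$edge.length, tolerance = 1e-12)
})

test_that("calibration fails on zero-height nodes and missing taxa", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_error(calibrate(tr, "A", "B", 1.7), "zero-height")
  tr2 <- upgma(random_distance_matrix(4, seed = 9))
  expect_error(calibrate(tr2, "t1", "nosuch", 1.7), "not in tree")
})

test_that("Robinson-Foulds distance counts discordant bipartitions", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(rf_distance(star, t1), 1)
  t3 <- read_newick("((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(rf_distance(t1, t3), "leaf sets")
})

test_that("genetic and epigenetic trees come from the stated matrices", {
  sim <- evolve(hominid_preset(seq_length = 3000, seed = 5))
  sc <- classify_alignment(sim$alignment)
  trees <- build_both_trees(sim$alignment, sc,
                            calibration = list(taxon_a = "chimp",
                                               taxon_b = "bonobo",
                                               age = 1.7))
  expect_equal(mrca_height(trees$genetic, "chimp", "bonobo"), 1.7,
               tolerance = 1e-9)
  expect_equal(mrca_height(trees$epigenetic, "chimp", "bonobo"), 1.7,
               tolerance = 1e-9)
  # identical route check: tree A is UPGMA of the full-alignment p-distance
  raw <- upgma(p_distance(sim$alignment))
  expect_equal(rf_distance(trees$genetic, raw), 0)
})

test_that("an alignment with no variation yields zero-height trees", {
  aln <- make_aln(c("CGATCGAT", "CGATCGAT", "CGATCGAT"))
  sc <- classify_alignment(aln)
  trees <- build_both_trees(aln, sc)
  expect_true(all(node_heights(trees$genetic) == 0))
  expect_true(all(node_heights(trees$epigenetic) == 0))
})

test_that("a single variable recoded column separates the two clusters", {
  aln <- make_aln(c("CGCG", "CGTG", "CGTG"))
  sc <- classify_alignment(aln)
  trees <- build_both_trees(aln, sc)
  expect_equal(mrca_height(trees$epigenetic, "B", "C"), 0)
  expect_gt(mrca_height(trees$epigenetic, "A", "B"), 0)
})
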