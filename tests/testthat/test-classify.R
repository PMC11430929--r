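test_that("site enumeration follows the chosen dinucleotide frame", {
  aln <- make_aln(c("ACGTAC", "ACGTAC"))
  non <- enumerate_sites(aln, "nonoverlapping")
  expect_equal(non$starts, c(1, 3, 5))
  ov <- enumerate_sites(aln, "overlapping")
  expect_equal(ov$starts, 1:5)
  expect_equal(ov$states[, 1], c("AC", "CG", "GT", "TA", "AC"))
})

test_that("single-site classification implements the CpG consistency rules", {
  cases <- list(
    list(c("CG", "CG", "CG"), "CONSISTENT_CPG"),
    list(c("CG", "TG", "CG"), "VARIABLE_CPG"),
    list(c("CA", "CA", "C-"), "GAPPED"),
    list(c("CG", "NG", "CG"), "GAPPED"),
    list(c("CA", "TA", "CA"), "NONCPG_VARIABLE"),
    list(c("AT", "AT", "AT"), "NONCPG_INVARIANT")
  )
  for (cs in cases)
    expect_equal(classify_site(cs[[1]]), cs[[2]])
  expect_error(classify_site(c("CGA", "CG")), "2 characters")
})

test_that("alignment classification matches hand enumeration", {
  sc <- classify_alignment(make_aln(c("CGCA", "CGTA", "CGCA")))
  expect_equal(sc$counts$n_cpg_sites, 1)
  expect_equal(sc$counts$n_consistent_cpg, 1)
  expect_equal(sc$counts$n_variable_cpg, 0)
  expect_equal(sc$counts$n_noncpg_variable, 1)
  expect_equal(sc$counts$n_noncpg_snp_columns, 1)

  # a CpG straddling the frame is only seen in overlapping mode
  aln <- make_aln(c("ACGT", "ACGT"))
  expect_equal(classify_alignment(aln, "nonoverlapping")$counts$n_cpg_sites, 0)
  expect_equal(classify_alignment(aln, "overlapping")$counts$n_cpg_sites, 1)

  # identical rows carry no variation anywhere
  sc0 <- classify_alignment(make_aln(c("CGCGAT", "CGCGAT")))
  expect_equal(sc0$counts$n_variable_cpg, 0)
  expect_equal(sc0$counts$n_noncpg_variable, 0)
  expect_equal(sc0$counts$n_noncpg_snp_columns, 0)
})

test_that("class counts always partition the dinucleotide sites", {
  for (seed in 1:10) {
    aln <- random_alignment(4, 50, seed = seed, cg_rich = TRUE)
    for (fm in c("nonoverlapping", "overlapping")) {
      sc <- classify_alignment(aln, fm)
      expect_equal(sum(table(factor(sc$class, levels = phyloepi:::SITE_CLASSES))),
                   sc$counts$n_dinuc_sites)
      expect_equal(sc$counts$n_cpg_sites,
                   sc$counts$n_consistent_cpg + sc$counts$n_variable_cpg)
    }
  }
})

test_that("overlapping mode finds at least the frame-anchored CpG sites", {
  for (seed in 11:20) {
    aln <- random_alignment(3, 40, seed = seed, cg_rich = TRUE)
    n_non <- classify_alignment(aln, "nonoverlapping")$counts$n_cpg_sites
    n_ov <- classify_alignment(aln, "overlapping")$counts$n_cpg_sites
    expect_gte(n_ov, n_non)
  }
})

test_that("classification recovers planted CpG sites at divergence zero", {
  cfg <- sim_config("(a:1,b:1);", seq_length = 400, cpg_fraction = 0.2,
                    seed = 42)
  root <- generate_root(cfg)
  aln <- new_alignment(c("a", "b"), c(root, root))
  sc <- classify_alignment(aln, "overlapping")
  found <- sc$starts[sc$class %in% c("CONSISTENT_CPG", "VARIABLE_CPG")]
  expect_identical(found, attr(root, "cpg_starts"))
})

test_that("summary fractions use the stated denominators and rounding", {
  fr <- summarize_fractions(list(n_cpg_sites = 2495, n_consistent_cpg = 2080))
  expect_equal(fr$percent_cpg_altered_report, 17)
  expect_equal(fr$percent_cpg_altered, 100 * 415 / 2495)

  fr0 <- summarize_fractions(list(n_cpg_sites = 10, n_variable_cpg = 0,
                                  n_dinuc_sites = 100, n_noncpg_variable = 7))
  expect_equal(fr0$percent_cpg_altered, 0)
  expect_equal(fr0$percent_dinuc_noncpg_variable, 7.0)

  frNA <- summarize_fractions(list(n_cpg_sites = 0, n_variable_cpg = 0))
  expect_true(is.na(frNA$percent_cpg_altered))
})

test_that("site report writes 0-based half-open coordinates with islands", {
  aln <- make_aln(c("CGCA", "CGTA", "CGCA"))
  sc <- classify_alignment(aln)
  f <- withr::local_tempfile(fileext = ".tsv")
  rmf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isl1\t0\t2", "isl2\t2\t4"), rmf)
  write_site_report(sc, f, region_map = read_region_map(rmf, aln$n_cols))
  rep <- read.delim(f)
  expect_equal(rep$start, c(0, 2))
  expect_equal(rep$end, c(2, 4))
  expect_equal(rep$island, c("isl1", "isl2"))
  expect_equal(rep$class, c("CONSISTENT_CPG", "NONCPG_VARIABLE"))
})
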