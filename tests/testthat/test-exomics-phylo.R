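small_am <- function(calls, reference = NULL, coverage = NULL) {
  calls <- as.matrix(calls)
  if (is.null(reference)) reference <- calls[, 1]
  if (is.null(coverage))
    coverage <- matrix(150L, nrow(calls), ncol(calls),
                       dimnames = dimnames(calls))
  allele_matrix(sprintf("c1:%d", seq_len(nrow(calls)) - 1), reference,
                calls, coverage)
}

test_that("locus filtering enforces coverage and variability", {
  calls <- cbind(s1 = c("A", "C", "G"), s2 = c("A", "T", "G"))
  cov <- cbind(s1 = c(99L, 100L, 500L), s2 = c(200L, 100L, 500L))
  am <- allele_matrix(c("t1:0", "t1:1", "t2:0"), c("A", "C", "G"), calls, cov)
  kept <- filter_loci(am, min_coverage = 100)
  # locus 1: one sample at coverage 99 -> removed even though variant-free too
  # locus 2: coverage exactly 100 everywhere and one variant call -> kept
  # locus 3: all calls equal the reference -> removed
  expect_identical(kept$locus_ids, "t1:1")
  expect_warning(filter_loci(am, min_coverage = 1000), "no loci")
  # any-sample coverage mode is more permissive
  am2 <- allele_matrix("t1:0", "A", cbind(s1 = "T", s2 = "A"),
                       cbind(s1 = 99L, s2 = 200L))
  expect_identical(length(filter_loci(am2, 100, all_samples = FALSE)$locus_ids), 1L)
  expect_warning(expect_identical(
    length(filter_loci(am2, 100, all_samples = TRUE)$locus_ids), 0L))
})

test_that("Hamming distances are pairwise-complete fractions", {
  am <- small_am(cbind(s = c("A", "C", "G", "T"), t = c("A", "C", "T", "T")),
                 reference = c("A", "C", "G", "T"))
  d <- hamming_matrix(am)
  expect_equal(d["s", "t"], 0.25)
  expect_equal(diag(d), c(s = 0, t = 0))
  # a missing call drops the locus from that pair only
  am2 <- small_am(cbind(s = c("A", "C", "G", "T"), t = c("A", "C", "N", "T"),
                        u = c("T", "G", "G", "A")))
  d2 <- hamming_matrix(am2)
  expect_equal(d2["s", "t"], 0 / 3)
  expect_equal(d2["s", "u"], 3 / 4)
  am3 <- small_am(cbind(s = c("A", "N"), t = c("N", "C")))
  expect_error(hamming_matrix(am3), "s.*t|no co-called")
  # identical samples stay at distance 0 under any locus subset
  am4 <- small_am(cbind(s = c("A", "C", "G"), t = c("A", "C", "G"),
                        u = c("T", "C", "G")))
  expect_equal(hamming_matrix(am4)["s", "t"], 0)
  sub <- allele_matrix(am4$locus_ids[1:2], am4$reference[1:2],
                       am4$calls[1:2, ], am4$coverage[1:2, ])
  expect_equal(hamming_matrix(sub)["s", "t"], 0)
})

test_that("UPGMA reproduces the hand-worked 4-taxon example", {
  d <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 6,
                6, 6, 6, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- upgma(d)
  expect_equal(tree$merges$height, c(1, 2, 3))
  expect_identical(to_newick(tree), "(((A:1,B:1):1,C:2):1,D:3);")
  # two leaves
  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_identical(to_newick(upgma(d2)), "(A:1,B:1);")
  expect_error(upgma(d2[1, 1, drop = FALSE]), "at least 2")
})

test_that("equal distances merge by the lexicographic tie rule", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tree <- upgma(d)
  expect_identical(tree$merges$left, c("A", "A", "A"))
  expect_identical(tree$merges$right, c("B", "C", "D"))
  expect_true(all(tree$merges$height == 0.5))
})

test_that("UPGMA trees are ultrametric and parse back from Newick", {
  set.seed(19)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(2 * n), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tree <- upgma(d)
    phy <- ape::read.tree(text = to_newick(tree))
    expect_true(ape::is.ultrametric(phy, tol = 1e-8))
    # independent cross-check: cophenetic distances match hclust average linkage
    hc <- stats::hclust(as.dist(d), method = "average")
    coph_hc <- as.matrix(stats::cophenetic(hc))
    coph_up <- as.matrix(ape::cophenetic.phylo(phy))
    expect_equal(coph_up[rownames(coph_hc), colnames(coph_hc)], coph_hc,
                 tolerance = 1e-8)
  }
})

test_that("allele matrices round-trip through TSV", {
  am <- generate_allele_matrix(n_loci = 40, mutation_rate = 0.3, seed = 8)
  f <- tempfile(fileext = ".tsv")
  write_allele_matrix(am, f)
  back <- read_allele_matrix(f)
  expect_identical(back$calls, am$calls)
  expect_identical(back$coverage, am$coverage)
  expect_identical(back$reference, am$reference)
  expect_identical(back$locus_ids, am$locus_ids)
})
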