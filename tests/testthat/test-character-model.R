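test_that("assignment probabilities follow the log-count rule", {
  expect_equal(assignment_probabilities(c(0, 1, 1)), c(0, 0.5, 0.5))
  expect_equal(assignment_probabilities(c(0, 9)), c(0, 1))
  # counts (3, 7, 15): weights log 4, log 8, log 16 = (2, 3, 4) in base 2
  expect_equal(assignment_probabilities(c(3, 7, 15)), c(2, 3, 4) / 9)
  expect_error(assignment_probabilities(c(0, 0)), "all counts are zero")
  expect_error(assignment_probabilities(c(-1, 2)), "non-negative")
})

test_that("multinomial resampling conserves reads and matches its law", {
  expect_identical(resample_reads(c(0, 1), 100), c(0L, 100L))
  set.seed(1)
  for (k in 1:20) {
    p <- assignment_probabilities(rpois(10, 20))
    expect_identical(sum(resample_reads(p, 500)), 500L)
  }
  # Monte-Carlo against the multinomial law: p = (.25, .75), R = 400
  set.seed(42)
  draws <- vapply(1:10000, function(i) resample_reads(c(.25, .75), 400),
                  integer(2))
  means <- rowMeans(draws)
  se <- sqrt(400 * c(.25, .75) * c(.75, .25) / 10000)
  expect_true(all(abs(means - c(100, 300)) < 3 * se))
  gof <- stats::chisq.test(rowSums(draws), p = c(.25, .75))
  expect_gt(gof$p.value, 0.001)
})

test_that("segmentation reproduces the worked example and forced cases", {
  # cumulative (100, 150, 160, 161): both 2-segmentations fit exactly after
  # position 2, giving bins (3, 3, 2, 2)
  a <- c(g1 = 100L, g2 = 50L, g3 = 10L, g4 = 1L)
  expect_identical(unname(segment_bins(a, P = 3)), c(3L, 3L, 2L, 2L))
  # a single expressed gene lands in bin P, the rest in bin 1
  b <- c(g1 = 0L, g2 = 7L, g3 = 0L)
  expect_identical(unname(suppressWarnings(segment_bins(b, P = 4))),
                   c(1L, 4L, 1L))
  # fewer nonzero genes than segments: one gene per bin from the top, warning
  cc <- c(g1 = 50L, g2 = 10L, g3 = 0L)
  expect_warning(bins <- segment_bins(cc, P = 5), "fewer nonzero")
  expect_identical(unname(bins), c(5L, 4L, 1L))
})

test_that("bins are invariant under uniform scaling of assigned counts", {
  set.seed(7)
  for (k in 1:10) {
    a <- rpois(60, 30); names(a) <- sprintf("g%02d", 1:60)
    expect_identical(segment_bins(a, P = 6), segment_bins(a * 10L, P = 6))
  }
})

test_that("segmentation DP equals exhaustive enumeration on random instances", {
  set.seed(11)
  for (k in 1:60) {
    n <- sample(4:12, 1)
    P <- sample(3:4, 1)
    counts <- sort(rpois(n, sample(c(5, 50), 1)) + 1, decreasing = TRUE)
    y <- cumsum(counts)
    dp <- rodeo:::cpp_segment_dp(as.numeric(seq_len(n)), y, P - 1)
    oracle <- oracle_segment(y, P - 1)
    expect_equal(dp$cost, oracle$cost, tolerance = 1e-8)
    expect_identical(dp$ends, as.integer(oracle$ends))
  }
})

test_that("every iteration satisfies the order and tie conditions", {
  set.seed(5)
  sim <- generate_two_condition_counts(n_genes = 300, n_de = 10, fold = 4,
                                       library_size = 2e4, seed = 5)
  p <- rodeo_params(P = 8, I = 10, seed = 5)
  phi <- estimate_phi(sim$table, "control_r1", p)
  for (i in seq_len(p$I)) {
    a <- phi$assigned[, i]; b <- phi$bin_matrix[, i]
    ord <- order(a)
    expect_true(all(diff(b[ord]) >= 0 | diff(a[ord]) == 0))
    # equal assigned counts => equal bins
    for (v in unique(a)) expect_length(unique(b[a == v]), 1L)
    # zero reads => bin 1
    expect_true(all(b[a == 0] == 1L))
  }
  expect_equal(unname(rowSums(phi$histogram)), rep(1, 300))
})

test_that("zero-count genes sit at bin 1 and top genes at bin P", {
  counts <- matrix(c(0L, 1000L, 120L, 100L, 80L, 60L, 40L, 20L, 10L, 5L),
                   ncol = 1, dimnames = list(sprintf("g%02d", 1:10), "s1"))
  tab <- count_table(cbind(counts, s2 = counts[, 1]))
  p <- rodeo_params(P = 4, I = 100, seed = 2, mode_threshold = 2)
  phi <- estimate_phi(tab, "s1", p)
  expect_equal(unname(phi$histogram["g01", 1]), 1.0)  # zero-count gene
  expect_gte(phi$histogram["g02", 4], 0.99)           # dominant gene
})

test_that("identical seeds give identical distributions, in any sample order", {
  tab <- count_table(matrix(rpois(40, 50) + 1L, 20, 2,
                            dimnames = list(sprintf("g%02d", 1:20),
                                            c("s1", "s2"))))
  p <- rodeo_params(P = 5, I = 8, seed = 9, mode_threshold = 3)
  a1 <- estimate_phi(tab, "s1", p)
  b1 <- estimate_phi(tab, "s2", p)
  b2 <- estimate_phi(tab, "s2", p)  # recompute out of order
  a2 <- estimate_phi(tab, "s1", p)
  expect_identical(a1, a2)
  expect_identical(b1, b2)
})

test_that("genes with identical counts have exchangeable histograms", {
  counts <- c(g1 = 200L, g2 = 200L, g3 = 50L, g4 = 800L, g5 = 10L)
  tab <- count_table(cbind(s1 = counts, s2 = counts))
  p <- rodeo_params(P = 4, I = 1000, seed = 13, mode_threshold = 2)
  phi <- estimate_phi(tab, "s1", p)
  tv <- 0.5 * sum(abs(phi$histogram["g1", ] - phi$histogram["g2", ]))
  expect_lt(tv, 0.1)
})

test_that("replicate averaging is the arithmetic mean of histograms", {
  b1 <- matrix(2L, 3, 4); b2 <- matrix(4L, 3, 4)
  rownames(b1) <- rownames(b2) <- paste0("g", 1:3)
  p1 <- make_phi(b1, P = 5); p2 <- make_phi(b2, P = 5)
  expect_identical(average_phi(list(p1)), p1)          # K = 1 identity
  avg <- average_phi(list(p1, p2))
  expect_equal(unname(avg$histogram[1, ]), c(0, .5, 0, .5, 0))
  expect_equal(unname(rowSums(avg$histogram)), rep(1, 3))
  expect_identical(ncol(avg$bin_matrix), 8L)
  rownames(b2) <- paste0("h", 1:3)
  expect_error(average_phi(list(p1, make_phi(b2, P = 5))), "gene set")
})
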