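truth_frame <- function(genes, logfc) data.frame(gene = genes, logfc = logfc,
                                                 stringsAsFactors = FALSE)

test_that("truth labels respect the strict cutoffs", {
  lab <- label_truth(truth_frame(c("a", "b", "c", "d"),
                                 c(1.6, 0.5, 1.2, -2.0)))
  expect_identical(lab$label, c("DE", "nonDE", "unassigned", "DE"))
  # boundary values stay unassigned (strict inequalities)
  lab <- label_truth(truth_frame(c("x", "y"), c(1.5, 1.0)))
  expect_identical(lab$label, c("unassigned", "unassigned"))
  expect_error(label_truth(truth_frame("a", 1), de_cutoff = 0.5,
                           nonde_cutoff = 1.0), "de_cutoff")
})

test_that("false-positive curves count non-DE genes in the labelled top x", {
  genes <- sprintf("g%02d", 1:20)
  lab <- label_truth(truth_frame(genes, c(rep(2, 10), rep(0.2, 10))))
  perfect <- genes
  expect_true(all(false_positive_curve(perfect, lab, 10)$fp == 0))
  worst <- genes[c(11:20, 1:10)]
  expect_identical(false_positive_curve(worst, lab, 10)$fp, 1:10)
  inter <- genes[as.vector(rbind(1:10, 11:20))]  # DE, nonDE, DE, ...
  expect_identical(false_positive_curve(inter, lab, 10)$fp,
                   as.integer(floor((1:10) / 2)))
  # unassigned genes are skipped without consuming positions
  lab2 <- label_truth(truth_frame(genes, c(rep(2, 5), rep(1.2, 10),
                                           rep(0.2, 5))))
  fp <- false_positive_curve(genes, lab2, 10)
  expect_identical(fp$fp, c(rep(0L, 5), 1:5))
})

test_that("AUC is the Mann-Whitney statistic with midrank ties", {
  genes <- c("a", "b", "c", "d")
  lab <- label_truth(truth_frame(genes, c(2, 0.1, 2, 0.1)))
  expect_equal(roc_auc(genes, lab)$auc, 0.75)  # worked 4-gene example
  # all DE ahead of all nonDE
  lab2 <- label_truth(truth_frame(genes, c(2, 2, 0.1, 0.1)))
  expect_equal(roc_auc(genes, lab2)$auc, 1.0)
  expect_error(roc_auc(genes, label_truth(truth_frame(genes, rep(2, 4)))),
               "at least one")
  # invariance under strictly monotone score transforms; pROC cross-check
  set.seed(6)
  sc <- runif(200); lf <- ifelse(rbinom(200, 1, .4) == 1, 2, 0.1)
  g <- sprintf("g%03d", 1:200)
  lab3 <- label_truth(truth_frame(g, lf))
  a1 <- roc_auc(g, lab3, scores = sc)$auc
  a2 <- roc_auc(g, lab3, scores = qlogis(sc))$auc
  expect_equal(a1, a2)
  skip_if_not_installed("pROC")
  a3 <- as.numeric(pROC::auc(pROC::roc(response = lf > 1, predictor = sc,
                                       quiet = TRUE, direction = "<")))
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(12)
  genes <- sprintf("g%04d", 1:2000)
  aucs <- vapply(1:50, function(k) {
    lf <- sample(c(rep(2, 1000), rep(0.1, 1000)))
    roc_auc(genes, label_truth(truth_frame(genes, lf)))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("FP and TP counts partition each labelled top x", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:100)
  lab <- label_truth(truth_frame(genes, sample(c(rep(2, 40), rep(.1, 60)))))
  ranked <- sample(genes)
  fp <- false_positive_curve(ranked, lab, 50)$fp
  keep <- ranked[match(ranked, lab$gene[lab$label != "unassigned"], 0) > 0]
  tp <- cumsum(lab$label[match(keep, lab$gene)] == "DE")[1:50]
  expect_identical(fp + tp, as.integer(1:50))
})

test_that("threshold sweeps relabel and degrade gracefully", {
  set.seed(14)
  g <- sprintf("g%03d", 1:300)
  lf <- abs(rnorm(300, 0, 1.2))
  ranked <- g[order(-lf)]          # ranking that follows |logFC| exactly
  sweep <- auc_threshold_sweep(ranked, truth_frame(g, lf),
                               thresholds = c(1.0, 1.5, 2.0, 50))
  expect_identical(sweep$threshold, c(1.0, 1.5, 2.0, 50))
  # consistency with the default labelling at threshold 1.5
  base <- roc_auc(ranked, label_truth(truth_frame(g, lf)))$auc
  expect_equal(sweep$auc[sweep$threshold == 1.5], base)
  # monotone signal: AUC is perfect at every feasible threshold
  expect_true(all(sweep$auc[1:3] == 1))
  expect_true(is.na(sweep$auc[4]))  # no DE genes left
  expect_error(auc_threshold_sweep(ranked, truth_frame(g, lf), c(2, 1)),
               "ascending")
})

test_that("top-x recovery matches direct counting", {
  g <- sprintf("g%02d", 1:30)
  lf <- seq(3, 0.1, length.out = 30)
  lab <- label_truth(truth_frame(g, lf))
  n_de <- sum(lab$label == "DE")
  # method ranking identical to truth ranking: y = x up to the DE count
  rec <- top_x_recovery(g, lab, 20)
  expect_identical(rec$recovered[1:n_de], 1:n_de)
  expect_true(all(rec$recovered <= rec$x))
  # reversed ranking: verified against a brute-force count
  rev_rank <- rev(g)
  rec2 <- top_x_recovery(rev_rank, lab, 20)
  labeled <- rev_rank[rev_rank %in% lab$gene[lab$label != "unassigned"]]
  truth_order <- lab$gene[lab$label == "DE"][order(-lf[lab$label == "DE"])]
  brute <- vapply(1:20, function(x)
    length(intersect(truth_order[seq_len(min(x, n_de))], labeled[1:x])), 0L)
  expect_identical(rec2$recovered, brute)
})
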