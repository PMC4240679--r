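#' Label truth genes from measured log-fold-changes
#'
#' A gene is labelled DE when |logFC| exceeds `de_cutoff`, non-DE when it is
#' below `nonde_cutoff`, and unassigned otherwise; evaluation metrics use only
#' the labelled genes.
#'
#' @param logfc data frame with columns `gene` and `logfc`.
#' @param de_cutoff,nonde_cutoff strict cutoffs (de_cutoff >= nonde_cutoff).
#' @return a data frame with columns gene, logfc, label; attribute `cutoffs`.
#' @export
label_truth <- function(logfc, de_cutoff = 1.5, nonde_cutoff = 1.0) {
  stopifnot(all(c("gene", "logfc") %in% colnames(logfc)))
  if (de_cutoff < nonde_cutoff)
    stop("de_cutoff must be >= nonde_cutoff")
  a <- abs(logfc$logfc)
  label <- ifelse(a > de_cutoff, "DE",
                  ifelse(a < nonde_cutoff, "nonDE", "unassigned"))
  out <- data.frame(gene = as.character(logfc$gene), logfc = logfc$logfc,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- c(de = de_cutoff, nonde = nonde_cutoff)
  out
}

restrict_to_labeled <- function(ranked_genes, labels) {
  lab <- labels$label[match(ranked_genes, labels$gene)]
  keep <- !is.na(lab) & lab != "unassigned"
  list(genes = ranked_genes[keep], label = lab[keep])
}

#' False positives among the top-ranked genes
#'
#' For each x, the number of truth-non-DE genes among the top x labelled
#' genes of the ranking; unassigned genes are skipped without consuming rank
#' positions.
#'
#' @param ranked_genes character vector, best-ranked first.
#' @param labels output of [label_truth()].
#' @param x_max largest list size to report.
#' @return data frame with columns `x` and `fp`.
#' @export
false_positive_curve <- function(ranked_genes, labels, x_max = 500) {
  r <- restrict_to_labeled(ranked_genes, labels)
  x <- seq_len(min(x_max, length(r$genes)))
  data.frame(x = x, fp = cumsum(r$label == "nonDE")[x])
}

#' ROC curve and AUC of a ranked gene list against truth labels
#'
#' AUC is the Mann-Whitney probability that a randomly chosen truth-DE gene
#' outranks a randomly chosen non-DE gene; score ties contribute 1/2
#' (midranks).
#'
#' @param ranked_genes character vector, best first.
#' @param labels output of [label_truth()].
#' @param scores optional numeric scores aligned with `ranked_genes` (higher
#'   = more DE); when omitted, the list positions define the scores and no
#'   ties occur.
#' @return list with `points` (data frame fpr, tpr) and `auc`.
#' @export
roc_auc <- function(ranked_genes, labels, scores = NULL) {
  if (is.null(scores)) scores <- -seq_along(ranked_genes)
  if (length(scores) != length(ranked_genes))
    stop("scores must align with ranked_genes")
  lab <- labels$label[match(ranked_genes, labels$gene)]
  keep <- !is.na(lab) & lab != "unassigned"
  s <- scores[keep]; pos <- lab[keep] == "DE"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("need at least one DE and one non-DE labelled gene")
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-s)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse tie groups so tied scores step diagonally
  last_of_group <- c(diff(s[ord]) != 0, TRUE)
  points <- data.frame(fpr = c(0, fp[last_of_group] / n0),
                       tpr = c(0, tp[last_of_group] / n1))
  list(points = points, auc = auc)
}

#' AUC while sweeping the DE-calling truth threshold
#'
#' Relabels the truth at each |logFC| threshold (the non-DE cutoff is scaled
#' proportionally, by default `nonde_ratio = 1.0 / 1.5`) and recomputes the
#' AUC of the same ranking; thresholds leaving a single truth class yield NA.
#'
#' @param ranked_genes character vector, best first.
#' @param logfc data frame with columns gene, logfc.
#' @param thresholds ascending numeric DE cutoffs.
#' @param nonde_ratio non-DE cutoff as a fraction of the DE cutoff.
#' @param scores optional scores, see [roc_auc()].
#' @return data frame with columns `threshold` and `auc`.
#' @export
auc_threshold_sweep <- function(ranked_genes, logfc, thresholds,
                                nonde_ratio = 1.0 / 1.5, scores = NULL) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  auc <- vapply(thresholds, function(t) {
    labels <- label_truth(logfc, de_cutoff = t, nonde_cutoff = t * nonde_ratio)
    res <- tryCatch(roc_auc(ranked_genes, labels, scores = scores),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$auc
  }, 0)
  data.frame(threshold = thresholds, auc = auc)
}

#' Recovery of the top truth genes within the method's top x
#'
#' The truth ranking orders the truth-DE genes by decreasing |logFC| (gene-id
#' tie-break). For each x, counts how many genes with truth rank <= x appear
#' within the method's top x labelled genes; the ideal curve is y = x.
#'
#' @param ranked_genes character vector, best first.
#' @param labels output of [label_truth()] (carries the logFC values).
#' @param x_max largest list size to report.
#' @return data frame with columns `x` and `recovered`.
#' @export
top_x_recovery <- function(ranked_genes, labels, x_max = 500) {
  r <- restrict_to_labeled(ranked_genes, labels)
  de <- labels[labels$label == "DE", ]
  truth_order <- de$gene[order(-abs(de$logfc), de$gene)]
  x <- seq_len(min(x_max, length(r$genes)))
  recovered <- vapply(x, function(k)
    length(intersect(truth_order[seq_len(min(k, length(truth_order)))],
                     r$genes[seq_len(k)])), 0L)
  data.frame(x = x, recovered = recovered)
}
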