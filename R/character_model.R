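#' Read-assignment probabilities from observed counts
#'
#' Each resampled read is assigned to gene g with probability proportional to
#' the logarithm of its observed count. The log is taken on `c_g + 1` so that
#' genes with zero observed reads get probability exactly 0 (they stay in bin
#' 1) while singletons can still receive reads; the base of the logarithm is
#' irrelevant after normalisation.
#'
#' @param counts non-negative numeric vector of observed read counts.
#' @return probability vector of the same length, summing to 1.
#' @export
assignment_probabilities <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  w <- log1p(counts)
  s <- sum(w)
  if (s == 0) stop("all counts are zero; assignment probabilities undefined")
  w / s
}

#' Draw one multinomial resampling iteration
#'
#' @param probabilities probability vector (non-negative, summing to 1).
#' @param R number of reads to draw (>= 1).
#' @return integer vector of assigned read counts, summing to `R`. Uses the
#'   current RNG state; seed upstream for reproducibility.
#' @export
resample_reads <- function(probabilities, R) {
  if (R < 1) stop("R must be >= 1")
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-6)
    stop("invalid probability vector")
  drawn <- as.integer(rmultinom(1, size = R, prob = probabilities)[, 1])
  names(drawn) <- names(probabilities)
  drawn
}

#' Segment assigned counts into P expression bins
#'
#' Genes are ordered by decreasing assigned count (ties broken by gene id);
#' genes with no assigned reads get bin 1. The cumulative sum of the ordered
#' nonzero counts is split into P-1 contiguous segments minimising the total
#' squared residual of per-segment least-squares lines; the first segment
#' (largest counts) maps to bin P, the next to P-1, and so on down to bin 2.
#' Runs of genes with identical assigned counts that straddle a segment
#' boundary are reassigned the bin held by the majority of the run (the higher
#' bin on a tie), so equal counts always receive equal bins.
#'
#' When the number of nonzero genes exceeds `subsample_threshold`, breakpoints
#' are fitted on every `subsample_step`-th ordered gene and mapped back by
#' position.
#'
#' @param assigned named integer vector of assigned read counts.
#' @param P number of bins (>= 2).
#' @param subsample_step,subsample_threshold see [rodeo_params()].
#' @param gene_ids identifiers used for deterministic tie-breaking; defaults
#'   to `names(assigned)`.
#' @return integer vector of bins in 1..P, in the input gene order.
#' @export
segment_bins <- function(assigned, P, subsample_step = 10,
                         subsample_threshold = 2000,
                         gene_ids = names(assigned)) {
  if (P < 2) stop("P must be >= 2")
  P <- as.integer(P)
  n_all <- length(assigned)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(n_all))
  bins <- rep(1L, n_all)
  nz <- which(assigned > 0)
  n <- length(nz)
  if (n == 0) return(stats::setNames(bins, gene_ids))

  ord <- nz[order(-assigned[nz], gene_ids[nz])]
  counts_sorted <- as.numeric(assigned[ord])
  nseg <- P - 1L

  if (n <= nseg) {
    # not enough genes for P-1 segments: one gene per segment from the top
    if (n < nseg)
      warning("fewer nonzero genes (", n, ") than segments (", nseg,
              "); assigning one gene per bin from bin P downwards")
    sorted_bins <- P - seq_len(n) + 1L
  } else {
    y <- cumsum(counts_sorted)
    if (n > subsample_threshold) {
      idx <- unique(c(seq(subsample_step, n, by = subsample_step), n))
    } else {
      idx <- seq_len(n)
    }
    if (length(idx) < nseg) idx <- seq_len(n)  # safety: never undersample
    fit <- cpp_segment_dp(as.numeric(idx), y[idx], nseg)
    ends <- idx[fit$ends]
    seg_id <- findInterval(seq_len(n) - 1L, ends) + 1L  # 1..nseg
    sorted_bins <- P - seg_id + 1L
  }

  # equal assigned counts must share a bin: majority vote per run, higher wins ties
  run <- cumsum(c(TRUE, diff(counts_sorted) != 0))
  for (r in unique(run[duplicated(run)])) {
    members <- which(run == r)
    b <- sorted_bins[members]
    if (length(unique(b)) > 1L) {
      tab <- table(b)
      winners <- as.integer(names(tab)[tab == max(tab)])
      sorted_bins[members] <- max(winners)
    }
  }

  bins[ord] <- sorted_bins
  stats::setNames(bins, gene_ids)
}

sample_stream_seed <- function(seed, sample_name) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(sample_name)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(max(1, h))
}

#' Estimate a gene-by-bin character-function distribution for one sample
#'
#' Runs `I` independent iterations of multinomial read resampling followed by
#' least-squares segmentation, and accumulates for every gene the empirical
#' histogram of its bin over iterations.
#'
#' The random stream is derived deterministically from the master seed and the
#' sample identifier, so samples can be processed in any order (or in
#' parallel) with identical results.
#'
#' @param table a [count_table()].
#' @param sample a sample identifier.
#' @param params a [rodeo_params()].
#' @return an object of class `phi_distribution` with elements `gene_ids`,
#'   `sample`, `P`, `I`, `bin_matrix` (L x I), `assigned` (L x I),
#'   `histogram` (L x P, rows summing to 1) and `averaged` (FALSE).
#' @export
estimate_phi <- function(table, sample, params) {
  stopifnot(inherits(table, "count_table"), inherits(params, "rodeo_params"))
  R <- resolve_R(table, params, sample)
  counts <- table$counts[, sample]
  prob <- assignment_probabilities(counts)
  L <- length(counts); I <- params$I; P <- params$P
  bin_matrix <- matrix(0L, L, I, dimnames = list(table$gene_ids, NULL))
  assigned_matrix <- matrix(0L, L, I, dimnames = list(table$gene_ids, NULL))
  base_seed <- sample_stream_seed(params$seed, sample)
  for (i in seq_len(I)) {
    set.seed((base_seed + i) %% 2147483647)
    assigned <- resample_reads(prob, R)
    assigned_matrix[, i] <- assigned
    bin_matrix[, i] <- segment_bins(assigned, P,
                                    subsample_step = params$subsample_step,
                                    subsample_threshold = params$subsample_threshold,
                                    gene_ids = table$gene_ids)
  }
  structure(list(gene_ids = table$gene_ids, sample = sample, P = P, I = I,
                 bin_matrix = bin_matrix, assigned = assigned_matrix,
                 histogram = bin_histogram(bin_matrix, P), averaged = FALSE),
            class = "phi_distribution")
}

bin_histogram <- function(bin_matrix, P) {
  h <- vapply(seq_len(P), function(p) rowSums(bin_matrix == p),
              numeric(nrow(bin_matrix)))
  h <- matrix(h, nrow = nrow(bin_matrix), ncol = P,
              dimnames = list(rownames(bin_matrix), paste0("bin", seq_len(P))))
  h / ncol(bin_matrix)
}

#' Average character functions over K replicates
#'
#' The replicate-averaged histogram is the arithmetic mean of the K replicate
#' histograms; the per-iteration bin and assigned-count matrices are retained
#' as column concatenations for use by dispersion and stable-gene analyses.
#'
#' @param phis list of `phi_distribution` objects over identical gene sets and
#'   P.
#' @return a `phi_distribution` with `averaged = TRUE` (identity for K = 1).
#' @export
average_phi <- function(phis) {
  if (inherits(phis, "phi_distribution")) phis <- list(phis)
  stopifnot(length(phis) >= 1)
  ref <- phis[[1]]
  for (p in phis) {
    if (!identical(p$gene_ids, ref$gene_ids))
      stop("replicates must share an identical gene set")
    if (p$P != ref$P) stop("replicates must share P")
  }
  if (length(phis) == 1) return(ref)
  hist <- Reduce(`+`, lapply(phis, `[[`, "histogram")) / length(phis)
  structure(list(gene_ids = ref$gene_ids,
                 sample = paste(vapply(phis, `[[`, "", "sample"),
                                collapse = "+"),
                 P = ref$P, I = sum(vapply(phis, `[[`, 0L, "I")),
                 bin_matrix = do.call(cbind, lapply(phis, `[[`, "bin_matrix")),
                 assigned = do.call(cbind, lapply(phis, `[[`, "assigned")),
                 histogram = hist, averaged = TRUE),
            class = "phi_distribution")
}

#' Write a character-function distribution to TSV
#'
#' Writes the gene x P histogram, and optionally the companion gene x I bin
#' matrix for reuse by dispersion and stable-gene analyses.
#'
#' @param phi a `phi_distribution`.
#' @param path histogram output path.
#' @param bins_path optional path for the bin matrix.
#' @export
write_phi <- function(phi, path, bins_path = NULL) {
  df <- data.frame(gene = phi$gene_ids, signif(phi$histogram, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bins_path)) {
    bm <- data.frame(gene = phi$gene_ids, phi$bin_matrix, check.names = FALSE)
    colnames(bm) <- c("gene", paste0("iter", seq_len(ncol(phi$bin_matrix))))
    write.table(bm, bins_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.phi_distribution <- function(x, ...) {
  cat("character-function distribution:", length(x$gene_ids), "genes, P =",
      x$P, ", I =", x$I,
      if (x$averaged) "(replicate-averaged)" else "", "\n")
  invisible(x)
}
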