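# Independent brute-force oracles and small fixture builders used across the
# test files. Oracles deliberately avoid the package's own code paths.

# residual sum of squares of a least-squares line through points (x, y)
oracle_line_sse <- function(x, y) {
  if (length(x) < 2) return(0)
  if (length(unique(x)) == 1) return(sum((y - mean(y))^2))
  fit <- stats::lm.fit(cbind(1, x), y)
  sum(fit$residuals^2)
}

# exhaustive least-squares segmentation: every placement of nseg-1 breakpoints
# over positions 1..n-1, in lexicographic order; returns the first placement
# attaining the minimal total error (within a relative tolerance).
oracle_segment <- function(y, nseg, x = seq_along(y), tol = 1e-9) {
  n <- length(y)
  stopifnot(nseg >= 1, n >= nseg)
  if (nseg == 1) return(list(ends = n, cost = oracle_line_sse(x, y)))
  placements <- utils::combn(n - 1, nseg - 1)
  costs <- apply(placements, 2, function(b) {
    ends <- c(b, n); starts <- c(1, b + 1)
    sum(vapply(seq_len(nseg), function(s)
      oracle_line_sse(x[starts[s]:ends[s]], y[starts[s]:ends[s]]), 0))
  })
  best <- min(costs)
  first <- which(costs <= best + tol * (1 + abs(best)))[1]
  list(ends = c(placements[, first], n), cost = best)
}

# brute-force LIS length via O(n^2) dynamic programming (independent of the
# patience-sorting implementation)
oracle_lis_length <- function(v) {
  n <- length(v)
  if (n == 0) return(0L)
  len <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    if (v[j] < v[i] && len[j] + 1L > len[i]) len[i] <- len[j] + 1L
  }
  max(len)
}

# all permutations of 1..n as a matrix with n! rows
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      p <- sub[r, ]
      p[p >= k] <- p[p >= k] + 1L
      out[row, ] <- c(k, p)
      row <- row + 1L
    }
  }
  out
}

# exhaustive LIS lengths for every row of a permutation matrix at once:
# for each subset mask, test strict increase across all rows vectorised
oracle_lis_lengths_all <- function(perms) {
  n <- ncol(perms)
  best <- rep(1L, nrow(perms))
  for (mask in seq_len(2^n - 1)) {
    pos <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    k <- length(pos)
    if (k < 2) next
    sub <- perms[, pos, drop = FALSE]
    inc <- rowSums(sub[, -1, drop = FALSE] > sub[, -k, drop = FALSE]) == k - 1
    best[inc & best < k] <- k
  }
  best
}

# a small deterministic count table
make_small_table <- function() {
  counts <- matrix(c(5L, 0L, 10L, 20L, 7L, 3L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  count_table(counts)
}

# build a phi_distribution directly from a bin matrix (for dispersion tests)
make_phi <- function(bin_matrix, P, assigned = NULL, sample = "x") {
  if (is.null(rownames(bin_matrix)))
    rownames(bin_matrix) <- paste0("g", seq_len(nrow(bin_matrix)))
  if (is.null(assigned)) assigned <- bin_matrix
  h <- vapply(seq_len(P), function(p) rowSums(bin_matrix == p),
              numeric(nrow(bin_matrix))) / ncol(bin_matrix)
  structure(list(gene_ids = rownames(bin_matrix), sample = sample, P = P,
                 I = ncol(bin_matrix), bin_matrix = bin_matrix,
                 assigned = assigned,
                 histogram = matrix(h, nrow(bin_matrix), P,
                                    dimnames = list(rownames(bin_matrix),
                                                    paste0("bin", 1:P))),
                 averaged = FALSE),
            class = "phi_distribution")
}

# random normalised histogram over P bins
random_histogram <- function(P) {
  h <- stats::rexp(P)
  h / sum(h)
}

write_tsv_text <- function(lines, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(lines, f)
  f
}
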