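#' Dispersion distribution between two character-function estimates
#'
#' Row p of the P x P dispersion matrix is the conditional distribution of a
#' gene's bin q in sample b given bin p in sample a, aggregated jointly over
#' all genes and all ordered iteration pairs (i, i'). When `self_mode = TRUE`
#' (a and b are the same estimate) the pairs with i = i' are excluded so that
#' neutrality is not inflated by comparing an iteration to itself.
#'
#' @param phiA,phiB `phi_distribution` objects over the same gene set and P.
#' @param self_mode logical; set when comparing an estimate to itself to
#'   obtain the within-sample dispersion (requires I >= 2).
#' @return an object of class `psi_matrix`: `matrix` (P x P, occupied rows
#'   sum to 1), `support` (pair counts per row), `summaries` (per-p
#'   over-expression O, under-expression U, neutrality N) and `self_mode`.
#' @export
compute_psi <- function(phiA, phiB, self_mode = FALSE) {
  stopifnot(inherits(phiA, "phi_distribution"),
            inherits(phiB, "phi_distribution"))
  if (!identical(phiA$gene_ids, phiB$gene_ids))
    stop("dispersion requires identical gene sets")
  if (phiA$P != phiB$P) stop("dispersion requires identical P")
  P <- phiA$P
  if (self_mode) {
    if (!identical(phiA$bin_matrix, phiB$bin_matrix))
      stop("self_mode requires comparing an estimate with itself")
    if (ncol(phiA$bin_matrix) < 2)
      stop("self_mode requires at least 2 iterations")
  }
  Na <- bin_counts(phiA$bin_matrix, P)
  Nb <- bin_counts(phiB$bin_matrix, P)
  pairs <- crossprod(Na, Nb)  # P x P counts over genes x ordered iteration pairs
  if (self_mode) {
    # remove the I diagonal pairs (i, i); their joint bin is always (p, p)
    diag(pairs) <- diag(pairs) - colSums(Na)
  }
  support <- rowSums(pairs)
  mat <- pairs
  occupied <- support > 0
  mat[occupied, ] <- mat[occupied, , drop = FALSE] / support[occupied]
  mat[!occupied, ] <- 0
  dimnames(mat) <- list(paste0("p", seq_len(P)), paste0("q", seq_len(P)))
  summaries <- data.frame(
    p = seq_len(P),
    O = vapply(seq_len(P), function(p)
      if (occupied[p]) sum(mat[p, seq_len(P) > p]) else NA_real_, 0),
    U = vapply(seq_len(P), function(p)
      if (occupied[p]) sum(mat[p, seq_len(P) < p]) else NA_real_, 0))
  summaries$N <- 1 - (summaries$O + summaries$U)
  structure(list(P = P, matrix = mat, support = as.numeric(support),
                 summaries = summaries, self_mode = self_mode),
            class = "psi_matrix")
}

bin_counts <- function(bin_matrix, P) {
  n <- vapply(seq_len(P), function(p) rowSums(bin_matrix == p),
              numeric(nrow(bin_matrix)))
  matrix(n, nrow = nrow(bin_matrix), ncol = P)
}

#' Over-, under-expression and neutrality summaries for one bin
#'
#' O is the probability mass on bins above p, U the mass below p, and the
#' neutrality N = 1 - (O + U) the mass staying at p. For a self-comparison
#' these are the within-sample dispersion measures used to judge the
#' stability of the character-function estimate (and to choose P).
#'
#' @param psi a `psi_matrix`.
#' @param p bin index in 1..P.
#' @return named numeric vector `c(O, U, N)`; all `NA` for an empty row.
#' @export
dispersion_summaries <- function(psi, p) {
  stopifnot(inherits(psi, "psi_matrix"))
  if (p < 1 || p > psi$P) stop("p must lie in 1..P")
  row <- psi$summaries[p, ]
  c(O = row$O, U = row$U, N = row$N)
}

#' Write a dispersion matrix and its summaries to TSV
#' @param psi a `psi_matrix`.
#' @param path output path for the P x P matrix.
#' @param summary_path optional path for the per-p (O, U, N) table.
#' @export
write_psi <- function(psi, path, summary_path = NULL) {
  df <- data.frame(p = seq_len(psi$P), signif(psi$matrix, 6),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- psi$summaries
    s[c("O", "U", "N")] <- lapply(s[c("O", "U", "N")], signif, digits = 6)
    write.table(s, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat("dispersion matrix: P =", x$P,
      if (x$self_mode) "(within-sample)" else "(cross-sample)", "\n")
  occ <- x$support > 0
  if (any(occ))
    cat("mean neutrality over occupied bins:",
        signif(mean(x$summaries$N[occ]), 4), "\n")
  invisible(x)
}
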