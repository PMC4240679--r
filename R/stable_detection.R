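#' Longest strictly increasing subsequence
#'
#' Patience sorting with a deterministic backtrace (each element records the
#' element currently on top of the previous pile; the subsequence is traced
#' back from the top of the last pile).
#'
#' @param seq numeric sequence of distinct values.
#' @return integer vector of indices of one maximum-length strictly
#'   increasing subsequence (empty for an empty input).
#' @export
longest_increasing_subsequence <- function(seq) {
  if (length(seq) == 0) return(integer(0))
  if (anyDuplicated(seq)) stop("sequence elements must be distinct")
  cpp_lis(as.numeric(seq))
}

#' Membership in any longest increasing subsequence
#'
#' @param seq numeric sequence of distinct values.
#' @return logical vector: `TRUE` where the element lies on at least one
#'   maximum-length strictly increasing subsequence.
#' @export
lis_members <- function(seq) {
  if (length(seq) == 0) return(logical(0))
  if (anyDuplicated(seq)) stop("sequence elements must be distinct")
  cpp_lis_members(as.numeric(seq))
}

#' Stable genes of one matched iteration pair
#'
#' Restricts to genes with at least one assigned read in both samples'
#' iteration ("active" genes), orders them by decreasing assigned count in
#' sample A (gene-id tie-break), takes the sequence of their ranks under
#' sample B's ordering, and returns the genes on the longest increasing
#' subsequence of that sequence — the genes whose relative expression order
#' is preserved between the two samples.
#'
#' @param assignedA,assignedB integer vectors of assigned read counts for one
#'   iteration of each sample, over the same gene universe.
#' @param gene_ids gene identifiers; default `names(assignedA)`.
#' @param method `"backtrace"` reports the deterministic LIS;
#'   `"union"` reports every gene lying on any LIS (quadratic cost, intended
#'   for moderate numbers of active genes).
#' @return character vector of stable gene ids (possibly empty).
#' @export
stable_pair <- function(assignedA, assignedB, gene_ids = names(assignedA),
                        method = c("backtrace", "union")) {
  method <- match.arg(method)
  if (length(assignedA) != length(assignedB))
    stop("assigned-count vectors must have equal length")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(assignedA))
  active <- assignedA > 0 & assignedB > 0
  if (!any(active)) return(character(0))
  ids <- gene_ids[active]
  a <- assignedA[active]; b <- assignedB[active]
  ordA <- order(-a, ids)
  ordB <- order(-b, ids)
  rankB <- integer(length(ids)); rankB[ordB] <- seq_along(ids)
  s <- rankB[ordA]
  if (method == "backtrace") {
    sort(ids[ordA][longest_increasing_subsequence(s)])
  } else {
    sort(ids[ordA][lis_members(s)])
  }
}

#' Stable genes across two samples
#'
#' Intersects the per-iteration stable sets of [stable_pair()] over the
#' matched iteration pairs (i, i), i = 1..I.
#'
#' @param phiA,phiB `phi_distribution` objects over the same gene set with
#'   equal iteration counts (their stored per-iteration assigned counts are
#'   used).
#' @param method passed to [stable_pair()].
#' @return an object of class `stable_set`: `stable` (the intersection),
#'   `per_iteration_sizes`, and `per_iteration` (the individual sets).
#' @export
stable_genes <- function(phiA, phiB, method = c("backtrace", "union")) {
  method <- match.arg(method)
  stopifnot(inherits(phiA, "phi_distribution"),
            inherits(phiB, "phi_distribution"))
  if (!identical(phiA$gene_ids, phiB$gene_ids))
    stop("stable-gene detection requires identical gene sets")
  if (ncol(phiA$assigned) != ncol(phiB$assigned))
    stop("stable-gene detection requires equal iteration counts")
  I <- ncol(phiA$assigned)
  sets <- lapply(seq_len(I), function(i)
    stable_pair(phiA$assigned[, i], phiB$assigned[, i],
                gene_ids = phiA$gene_ids, method = method))
  structure(list(stable = sort(Reduce(intersect, sets)),
                 per_iteration_sizes = lengths(sets),
                 per_iteration = sets, method = method),
            class = "stable_set")
}

#' @export
print.stable_set <- function(x, ...) {
  cat("stable set:", length(x$stable), "genes (intersection over",
      length(x$per_iteration_sizes), "iterations; per-iteration sizes",
      min(x$per_iteration_sizes), "-", max(x$per_iteration_sizes), ")\n")
  invisible(x)
}
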