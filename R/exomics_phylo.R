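#' Construct an allele-call matrix
#'
#' Loci are identified as `transcript:position` with 0-based positions within
#' the transcript. Allele symbols are A/C/G/T; `N` (or `NA`) marks a missing
#' or ambiguous call and is excluded from distance computations.
#'
#' @param locus_ids unique locus identifiers.
#' @param reference reference allele per locus.
#' @param calls character matrix (loci x samples) of allele calls.
#' @param coverage integer matrix (loci x samples) of read coverage.
#' @return an object of class `allele_matrix`.
#' @export
allele_matrix <- function(locus_ids, reference, calls, coverage) {
  calls <- as.matrix(calls); coverage <- as.matrix(coverage)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(locus_ids))
    stop("duplicate locus id: ", locus_ids[duplicated(locus_ids)][1])
  if (length(reference) != length(locus_ids) ||
      nrow(calls) != length(locus_ids) ||
      !identical(dim(calls), dim(coverage)))
    stop("allele matrix dimensions are inconsistent")
  ok <- c("A", "C", "G", "T", "N")
  bad <- calls[!is.na(calls) & !(calls %in% ok)]
  if (length(bad)) stop("invalid allele symbol: ", bad[1])
  if (any(coverage < 0, na.rm = TRUE)) stop("coverage must be >= 0")
  rownames(calls) <- rownames(coverage) <- locus_ids
  structure(list(locus_ids = locus_ids, reference = as.character(reference),
                 sample_ids = colnames(calls), calls = calls,
                 coverage = coverage),
            class = "allele_matrix")
}

#' Read an allele matrix from TSV
#'
#' Expected columns: `locus`, `reference`, then `<sample>_allele` and
#' `<sample>_coverage` per sample.
#'
#' @param path path to the TSV.
#' @return an `allele_matrix`.
#' @export
read_allele_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  allele_cols <- grep("_allele$", colnames(df), value = TRUE)
  samples <- sub("_allele$", "", allele_cols)
  calls <- as.matrix(df[, paste0(samples, "_allele"), drop = FALSE])
  coverage <- as.matrix(df[, paste0(samples, "_coverage"), drop = FALSE])
  colnames(calls) <- colnames(coverage) <- samples
  allele_matrix(df$locus, df$reference, calls, coverage)
}

#' Write an allele matrix to TSV
#' @param am an `allele_matrix`.
#' @param path output path.
#' @export
write_allele_matrix <- function(am, path) {
  stopifnot(inherits(am, "allele_matrix"))
  df <- data.frame(locus = am$locus_ids, reference = am$reference,
                   stringsAsFactors = FALSE)
  for (s in am$sample_ids) {
    df[[paste0(s, "_allele")]] <- am$calls[, s]
    df[[paste0(s, "_coverage")]] <- am$coverage[, s]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter loci by coverage and variability
#'
#' Keeps loci where every non-missing sample reaches `min_coverage` reads
#' (or at least one sample, when `all_samples = FALSE`) and where at least
#' one sample's call differs from the reference allele.
#'
#' @param am an `allele_matrix`.
#' @param min_coverage minimum read coverage (default 100).
#' @param all_samples require the coverage of every non-missing sample
#'   (default) rather than of at least one.
#' @return the filtered `allele_matrix` (warns when empty).
#' @export
filter_loci <- function(am, min_coverage = 100, all_samples = TRUE) {
  stopifnot(inherits(am, "allele_matrix"))
  present <- !is.na(am$calls) & am$calls != "N"
  covered <- am$coverage >= min_coverage
  cov_ok <- if (all_samples) {
    rowSums(present & !covered) == 0 & rowSums(present) > 0
  } else {
    rowSums(present & covered) > 0
  }
  variant <- rowSums(present & (am$calls != am$reference)) > 0
  keep <- cov_ok & variant
  if (!any(keep)) warning("no loci pass the filters; empty allele matrix")
  out <- allele_matrix(am$locus_ids[keep], am$reference[keep],
                       am$calls[keep, , drop = FALSE],
                       am$coverage[keep, , drop = FALSE])
  out$truth_tree <- am$truth_tree
  out
}

#' Pairwise Hamming distances between samples
#'
#' For samples s and t, the fraction of loci where both calls are present and
#' differ, among the loci where both are present (pairwise-complete
#' normalisation, so distances are comparable across locus subsets).
#'
#' @param am an `allele_matrix` with >= 2 samples and >= 1 locus.
#' @return symmetric numeric matrix with zero diagonal, entries in \[0, 1\].
#' @export
hamming_matrix <- function(am) {
  stopifnot(inherits(am, "allele_matrix"))
  S <- length(am$sample_ids)
  if (S < 2 || length(am$locus_ids) < 1)
    stop("need at least 2 samples and 1 locus")
  present <- !is.na(am$calls) & am$calls != "N"
  d <- matrix(0, S, S, dimnames = list(am$sample_ids, am$sample_ids))
  for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) {
    both <- present[, i] & present[, j]
    n <- sum(both)
    if (n == 0)
      stop("samples '", am$sample_ids[i], "' and '", am$sample_ids[j],
           "' share no co-called loci; distance undefined")
    d[i, j] <- d[j, i] <- sum(am$calls[both, i] != am$calls[both, j]) / n
  }
  d
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance between two
#' clusters is the arithmetic mean of the distances over all member pairs,
#' and each merge is placed at height d/2, yielding a rooted ultrametric
#' tree. Ties are resolved by merging the pair whose (lexicographically
#' smallest member, other member) labels sort first.
#'
#' @param dist symmetric non-negative matrix with zero diagonal and labelled
#'   rows/columns (>= 2 samples).
#' @return an object of class `upgma_tree`: `root` (nested node list with
#'   `height`, `left`, `right` or `label`), `merges` (data frame of merge
#'   heights in merge order) and `leaves`.
#' @export
upgma <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 2) stop("need at least 2 samples")
  if (is.null(rownames(dist))) stop("distance matrix must be labelled")
  if (!isSymmetric(unname(dist)) || any(diag(dist) != 0) || any(dist < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  labels <- rownames(dist)
  clusters <- lapply(seq_len(n), function(i) list(
    members = labels[i], repr = labels[i], size = 1L,
    node = list(label = labels[i], height = 0)))
  d <- dist
  merges <- data.frame(step = integer(0), left = character(0),
                       right = character(0), height = numeric(0),
                       stringsAsFactors = FALSE)
  step <- 0L
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      pr <- sort(c(clusters[[i]]$repr, clusters[[j]]$repr))
      cand <- list(i = i, j = j, d = d[i, j], key = pr)
      if (is.null(best) || cand$d < best$d ||
          (cand$d == best$d &&
           (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
        best <- cand
    }
    i <- best$i; j <- best$j
    ci <- clusters[[i]]; cj <- clusters[[j]]
    # average-linkage update (weights must track the matrix indices i and j,
    # independent of the display order of the children)
    others <- setdiff(seq_len(m), c(i, j))
    newd <- vapply(others, function(k)
      (ci$size * d[i, k] + cj$size * d[j, k]) / (ci$size + cj$size), 0)
    height <- best$d / 2
    # child whose representative sorts first goes left
    if (ci$repr > cj$repr) { tmp <- ci; ci <- cj; cj <- tmp }
    node <- list(height = height, left = ci$node, right = cj$node)
    merged <- list(members = sort(c(ci$members, cj$members)),
                   repr = min(ci$repr, cj$repr),
                   size = ci$size + cj$size, node = node)
    step <- step + 1L
    merges <- rbind(merges, data.frame(step = step, left = ci$repr,
                                       right = cj$repr, height = height,
                                       stringsAsFactors = FALSE))
    keep <- d[others, others, drop = FALSE]
    d <- rbind(cbind(keep, newd), c(newd, 0))
    clusters <- c(clusters[others], list(merged))
  }
  structure(list(root = clusters[[1]]$node, merges = merges,
                 leaves = sort(labels)),
            class = "upgma_tree")
}

#' Newick serialisation of a UPGMA tree
#'
#' Branch lengths are differences between parent and child heights; the
#' string is terminated by ";".
#'
#' @param tree an `upgma_tree`.
#' @return a single Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  fmt <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  rec <- function(node, parent_height) {
    if (!is.null(node$label))
      return(paste0(node$label, ":", fmt(parent_height)))
    paste0("(", rec(node$left, node$height), ",",
           rec(node$right, node$height), "):",
           fmt(parent_height - node$height))
  }
  root <- tree$root
  if (!is.null(root$label)) return(paste0(root$label, ";"))
  paste0("(", rec(root$left, root$height), ",",
         rec(root$right, root$height), ");")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", length(x$leaves), "samples\n")
  cat(to_newick(x), "\n")
  invisible(x)
}
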