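#' Maximum-norm distance between two bin histograms
#'
#' The largest absolute difference between the cumulative bin distributions —
#' the Kolmogorov-Smirnov statistic on the discrete bins.
#'
#' @param hA,hB numeric histograms of equal length, each summing to 1.
#' @return a number in \[0, 1\].
#' @export
maxnorm_distance <- function(hA, hB) {
  if (length(hA) != length(hB)) stop("histograms must have equal length")
  max(abs(cumsum(hA) - cumsum(hB)))
}

#' Mode of a bin histogram
#'
#' The smallest bin index attaining the maximum frequency.
#'
#' @param h numeric histogram.
#' @return a bin index.
#' @export
mode_of <- function(h) which.max(h)

#' Per-gene DE records from two character-function distributions
#'
#' Computes for every gene the max-norm distance between its histograms in
#' the two samples, both modes, the mode distance, and the direction of
#' change (`up` means a higher mode in sample b).
#'
#' @param phiA,phiB `phi_distribution` objects over the same gene set and P
#'   (replicate-averaged if K > 1).
#' @return a data frame with columns gene, maxnorm, mode_a, mode_b,
#'   mode_distance, direction.
#' @export
de_records <- function(phiA, phiB) {
  stopifnot(inherits(phiA, "phi_distribution"),
            inherits(phiB, "phi_distribution"))
  if (!identical(phiA$gene_ids, phiB$gene_ids))
    stop("DE comparison requires identical gene sets")
  if (phiA$P != phiB$P) stop("DE comparison requires identical P")
  CA <- t(apply(phiA$histogram, 1, cumsum))
  CB <- t(apply(phiB$histogram, 1, cumsum))
  maxnorm <- apply(abs(CA - CB), 1, max)
  mode_a <- max.col(phiA$histogram, ties.method = "first")
  mode_b <- max.col(phiB$histogram, ties.method = "first")
  direction <- ifelse(mode_b > mode_a, "up",
                      ifelse(mode_b < mode_a, "down", "none"))
  data.frame(gene = phiA$gene_ids, maxnorm = unname(maxnorm),
             mode_a = mode_a, mode_b = mode_b,
             mode_distance = abs(mode_a - mode_b),
             direction = direction, stringsAsFactors = FALSE)
}

#' Rank genes by decreasing max-norm distance
#'
#' Ties in max-norm are broken by decreasing mode distance, then by gene id.
#'
#' @param records a data frame from [de_records()].
#' @return the records sorted into rank order with a `rank` column (1..L).
#' @export
rank_genes <- function(records) {
  ord <- order(-records$maxnorm, -records$mode_distance, records$gene)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Call differentially expressed genes
#'
#' A gene is called DE when its max-norm distance reaches the threshold
#' \eqn{\delta} (within `epsilon`) and its mode distance reaches the mode
#' threshold.
#'
#' @param records ranked records from [rank_genes()].
#' @param params a [rodeo_params()].
#' @return the records with an `is_DE` column added.
#' @export
call_de <- function(records, params) {
  stopifnot(inherits(params, "rodeo_params"))
  records$is_DE <- records$maxnorm >= params$dist_threshold - params$epsilon &
    records$mode_distance >= params$mode_threshold
  records
}

#' Descending ranking scores for evaluation
#'
#' Converts the (maxnorm, mode distance) ranking keys into a single numeric
#' score, higher = more DE; records with identical keys receive identical
#' (midrank-style) scores so downstream AUC treats them as tied.
#'
#' @param records a data frame from [de_records()].
#' @return numeric vector aligned with `records`.
#' @export
de_scores <- function(records) {
  ord <- order(-records$maxnorm, -records$mode_distance, records$gene)
  key_sorted <- paste(records$maxnorm[ord], records$mode_distance[ord])
  grp <- cumsum(!duplicated(key_sorted))
  score_sorted <- -stats::ave(seq_along(grp), grp)
  score <- numeric(nrow(records))
  score[ord] <- score_sorted
  score
}

#' Intersect DE sets into robust sets
#'
#' A robust up- (down-) regulated gene of a group is one called up (down) in
#' every member of the group — e.g. in both cultivars sharing a positive
#' stress response. Cross-group overlaps of the robust sets are reported as
#' well.
#'
#' @param de_sets named list; each element is a list with character vectors
#'   `up` and `down` (the member's called DE genes by direction).
#' @param groups named list mapping a group label to >= 2 member names of
#'   `de_sets`.
#' @return a list with one element per group (`up`, `down` robust sets) plus
#'   `overlaps`, a data frame of pairwise robust-set intersection sizes.
#' @export
robust_sets <- function(de_sets, groups) {
  for (g in names(groups)) {
    members <- groups[[g]]
    if (length(members) < 2)
      stop("group '", g, "' has fewer than 2 members; robust set undefined")
    if (!all(members %in% names(de_sets)))
      stop("group '", g, "' references unknown DE sets: ",
           paste(setdiff(members, names(de_sets)), collapse = ", "))
  }
  out <- lapply(groups, function(members) {
    list(up = sort(Reduce(intersect, lapply(de_sets[members], `[[`, "up"))),
         down = sort(Reduce(intersect, lapply(de_sets[members], `[[`, "down"))))
  })
  gl <- names(groups)
  overlaps <- data.frame(group_a = character(0), group_b = character(0),
                         direction = character(0), overlap = integer(0),
                         stringsAsFactors = FALSE)
  if (length(gl) >= 2) {
    for (i in seq_len(length(gl) - 1)) for (j in seq(i + 1, length(gl))) {
      for (dir in c("up", "down")) {
        overlaps <- rbind(overlaps, data.frame(
          group_a = gl[i], group_b = gl[j], direction = dir,
          overlap = length(intersect(out[[gl[i]]][[dir]],
                                     out[[gl[j]]][[dir]])),
          stringsAsFactors = FALSE))
      }
    }
  }
  c(out, list(overlaps = overlaps))
}
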