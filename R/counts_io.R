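#' Construct a validated count table
#'
#' A count table holds the observed read counts `c_g` of L genes across S
#' samples, plus the per-sample totals M. Counts must be non-negative
#' integers; gene and sample identifiers must be unique.
#'
#' @param counts numeric matrix (genes x samples) of non-negative integers.
#' @param gene_ids,sample_ids identifiers; default to the dimnames.
#' @return an object of class `count_table` with elements `gene_ids`,
#'   `sample_ids`, `counts` (integer matrix with dimnames) and `totals`.
#' @export
count_table <- function(counts, gene_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids); sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(sample_ids))
    stop("dimensions of counts do not match the identifiers")
  if (nrow(counts) < 2) stop("a count table needs at least 2 genes")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id: ", dup[1])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(counts)) + 1
    j <- ((bad[1] - 1) %/% nrow(counts)) + 1
    stop(sprintf(
      "invalid count %s at gene '%s', sample '%s' (must be a non-negative integer)",
      format(counts[i, j]), gene_ids[i], sample_ids[j]))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 counts = counts, totals = colSums(counts)),
            class = "count_table")
}

#' Read a count table from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers, followed by one integer column per sample. Input gene order
#' is preserved.
#'
#' @param path path to a tab-separated file.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty count table: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    nonnum <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                                 as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 df[[1]][nonnum[1, 1]], colnames(df)[-1][nonnum[1, 2]]))
  }
  count_table(m, gene_ids = df[[1]], sample_ids = colnames(df)[-1])
}

#' Write a count table to TSV
#'
#' @param table a [count_table()].
#' @param path output path.
#' @param gene_column name of the identifier column (first column).
#' @export
write_count_table <- function(table, path, gene_column = "gene") {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(table$gene_ids, table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(gene_column, table$sample_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve the number of reads drawn per resampling iteration
#'
#' A numeric `R` applies to every sample; `R = "auto"` resolves to the
#' sample's own total of mapped reads.
#'
#' @param table a [count_table()].
#' @param params a [rodeo_params()].
#' @param sample a sample identifier present in `table`.
#' @return a positive integer-valued number.
#' @export
resolve_R <- function(table, params, sample) {
  stopifnot(inherits(table, "count_table"))
  if (!sample %in% table$sample_ids) stop("unknown sample: ", sample)
  if (is.numeric(params$R)) return(params$R)
  total <- table$totals[[sample]]
  if (total == 0)
    stop("sample '", sample, "' has zero total reads; cannot resample")
  total
}

#' @export
print.count_table <- function(x, ...) {
  cat("count table:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("per-sample totals:",
      paste(sprintf("%s=%d", x$sample_ids, x$totals), collapse = ", "), "\n")
  invisible(x)
}

# ---- experiment design ------------------------------------------------------

#' Describe samples, conditions, replicates and comparisons
#'
#' @param sample_id,condition,replicate parallel vectors; replicates within a
#'   condition must be numbered 1..K without gaps.
#' @param comparisons list of length-2 character vectors of condition labels
#'   (a, b); `b` is the treatment/stress side of each comparison.
#' @param groups optional named list mapping a response/time group label to
#'   the condition-pair names belonging to it (used for robust sets).
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(sample_id, condition, replicate = NULL,
                              comparisons = list(), groups = NULL) {
  sample_id <- as.character(sample_id); condition <- as.character(condition)
  if (length(sample_id) != length(condition))
    stop("sample_id and condition must have equal length")
  if (anyDuplicated(sample_id)) stop("duplicate sample id in design")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  for (cond in unique(condition)) {
    k <- sort(replicate[condition == cond])
    if (!identical(k, seq_along(k)))
      stop("replicates of condition '", cond, "' must be numbered 1..K")
  }
  for (cmp in comparisons) {
    if (length(cmp) != 2 || cmp[1] == cmp[2])
      stop("each comparison must name two distinct conditions")
    if (!all(cmp %in% condition))
      stop("comparison references unknown condition: ",
           paste(setdiff(cmp, condition), collapse = ", "))
  }
  structure(list(samples = data.frame(sample_id = sample_id,
                                      condition = condition,
                                      replicate = replicate,
                                      stringsAsFactors = FALSE),
                 comparisons = comparisons, groups = groups),
            class = "experiment_design")
}

#' Check that a design matches a count table
#' @param design an [experiment_design()].
#' @param table a [count_table()].
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_design <- function(design, table) {
  stopifnot(inherits(design, "experiment_design"), inherits(table, "count_table"))
  missing <- setdiff(design$samples$sample_id, table$sample_ids)
  if (length(missing))
    stop("design samples absent from count table: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

condition_samples <- function(design, cond) {
  s <- design$samples
  s$sample_id[s$condition == cond][order(s$replicate[s$condition == cond])]
}

# ---- DE result tables -------------------------------------------------------

#' Write a ranked DE table to TSV
#'
#' Columns: gene, maxnorm, mode_a, mode_b, mode_distance, direction, rank,
#' is_DE; rows in rank order. Floating-point values are written with 6
#' significant digits.
#'
#' @param records a ranked data frame as produced by [call_de()].
#' @param path output path.
#' @export
write_de_table <- function(records, path) {
  cols <- c("gene", "maxnorm", "mode_a", "mode_b", "mode_distance",
            "direction", "rank", "is_DE")
  if (nrow(records) > 0) {
    stopifnot(all(cols %in% colnames(records)))
    records <- records[order(records$rank), cols]
    records$maxnorm <- signif(records$maxnorm, 6)
  } else {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                      cols))
  }
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a DE table written by [write_de_table()]
#' @param path path to the TSV.
#' @return a data frame in rank order.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = c(gene = "character"))
  df$is_DE <- as.logical(df$is_DE)
  df
}
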