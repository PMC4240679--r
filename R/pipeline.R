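#' @name pipeline
#' @title End-to-end pipeline runs
#' @description `run_de()`, `run_stable()` and `run_phylo()` orchestrate the
#'   resampling, ranking, stable-gene and phylogeny stages over an output
#'   directory, writing result tables and a machine-readable run manifest.
#'   All randomness flows from the single seed in the parameters, with
#'   per-sample substreams, so reruns with the same inputs are byte-identical
#'   in every result table.
NULL

condition_phi <- function(table, design, cond, params) {
  samples <- condition_samples(design, cond)
  average_phi(lapply(samples, function(s) estimate_phi(table, s, params)))
}

write_manifest <- function(outdir, params, inputs, outputs, extra = list()) {
  manifest <- c(list(
    parameters = params[setdiff(names(params), NULL)],
    seed = params$seed,
    inputs = inputs,
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Run the differential-expression pipeline
#'
#' For every comparison (a, b) in the design: estimates the
#' character-function distribution of each side (replicate-averaged when
#' K > 1), writes the histograms, within-sample dispersion diagnostics, the
#' ranked DE table and the called up/down gene lists, then writes a run
#' manifest.
#'
#' @param table a [count_table()].
#' @param design an [experiment_design()] with at least one comparison.
#' @param params a [rodeo_params()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the per-comparison called records and the
#'   manifest.
#' @export
run_de <- function(table, design, params, outdir) {
  validate_design(design, table)
  if (!length(design$comparisons)) stop("design lists no comparisons")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0); results <- list()
  for (cmp in design$comparisons) {
    a <- cmp[1]; b <- cmp[2]
    tag <- paste0(a, "_vs_", b)
    message("[de] comparison ", tag)
    phiA <- condition_phi(table, design, a, params)
    phiB <- condition_phi(table, design, b, params)
    f_phi_a <- file.path(outdir, paste0("phi_", a, ".tsv"))
    f_phi_b <- file.path(outdir, paste0("phi_", b, ".tsv"))
    write_phi(phiA, f_phi_a); write_phi(phiB, f_phi_b)
    psi_ab <- compute_psi(phiA, phiB)
    psi_self <- compute_psi(phiA, phiA, self_mode = TRUE)
    f_psi <- file.path(outdir, paste0("psi_", tag, ".tsv"))
    f_psi_sum <- file.path(outdir, paste0("psi_", tag, "_summary.tsv"))
    f_self <- file.path(outdir, paste0("psi_self_", a, "_summary.tsv"))
    write_psi(psi_ab, f_psi, f_psi_sum)
    write_psi(psi_self, file.path(outdir, paste0("psi_self_", a, ".tsv")),
              f_self)
    records <- call_de(rank_genes(de_records(phiA, phiB)), params)
    f_de <- file.path(outdir, paste0("de_", tag, ".tsv"))
    write_de_table(records, f_de)
    up <- records$gene[records$is_DE & records$direction == "up"]
    down <- records$gene[records$is_DE & records$direction == "down"]
    f_up <- file.path(outdir, paste0("de_", tag, "_up.txt"))
    f_down <- file.path(outdir, paste0("de_", tag, "_down.txt"))
    writeLines(up, f_up); writeLines(down, f_down)
    outputs <- c(outputs, f_phi_a, f_phi_b, f_psi, f_psi_sum, f_self, f_de,
                 f_up, f_down)
    results[[tag]] <- records
  }
  manifest <- write_manifest(outdir, params,
                             inputs = list(genes = length(table$gene_ids),
                                           samples = table$sample_ids),
                             outputs = unique(outputs))
  invisible(list(results = results, manifest = manifest))
}

#' Run the stable-gene pipeline
#'
#' Per comparison, writes the intersected stable gene list and a diagnostic
#' table of per-iteration stable-set sizes.
#'
#' @inheritParams run_de
#' @return invisibly, per-comparison `stable_set` objects and the manifest.
#' @export
run_stable <- function(table, design, params, outdir) {
  validate_design(design, table)
  if (!length(design$comparisons)) stop("design lists no comparisons")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0); results <- list()
  for (cmp in design$comparisons) {
    a <- cmp[1]; b <- cmp[2]
    tag <- paste0(a, "_vs_", b)
    message("[stable] comparison ", tag)
    phiA <- condition_phi(table, design, a, params)
    phiB <- condition_phi(table, design, b, params)
    ss <- stable_genes(phiA, phiB)
    f_list <- file.path(outdir, paste0("stable_", tag, ".txt"))
    writeLines(ss$stable, f_list)
    f_sizes <- file.path(outdir, paste0("stable_", tag, "_sizes.tsv"))
    write.table(data.frame(iteration = seq_along(ss$per_iteration_sizes),
                           size = ss$per_iteration_sizes),
                f_sizes, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f_list, f_sizes)
    results[[tag]] <- ss
  }
  manifest <- write_manifest(outdir, params,
                             inputs = list(genes = length(table$gene_ids),
                                           samples = table$sample_ids),
                             outputs = unique(outputs))
  invisible(list(results = results, manifest = manifest))
}

#' Run the comparative-exomics phylogeny pipeline
#'
#' For each locus subset (e.g. all / DE / stable transcripts), filters loci
#' by coverage and variability, computes pairwise allele Hamming distances
#' and the average-linkage dendrogram, and writes the distance matrix and the
#' Newick tree.
#'
#' @param am an [allele_matrix()].
#' @param subsets named list; each element is either `NULL` (all loci) or a
#'   character vector of transcript ids (loci whose `transcript:position` id
#'   has a matching transcript are kept). Unknown transcript ids produce a
#'   warning and are ignored.
#' @param outdir output directory.
#' @param min_coverage coverage filter passed to [filter_loci()].
#' @param params optional [rodeo_params()] echoed into the manifest.
#' @return invisibly, per-subset `upgma_tree` objects and the manifest.
#' @export
run_phylo <- function(am, subsets = list(all = NULL), outdir,
                      min_coverage = 100, params = rodeo_params()) {
  stopifnot(inherits(am, "allele_matrix"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  transcripts <- sub(":.*$", "", am$locus_ids)
  outputs <- character(0); results <- list()
  for (name in names(subsets)) {
    sub_am <- am
    wanted <- subsets[[name]]
    if (!is.null(wanted)) {
      unknown <- setdiff(wanted, transcripts)
      if (length(unknown))
        warning("subset '", name, "': ignoring unknown transcripts: ",
                paste(head(unknown, 5), collapse = ", "))
      keep <- transcripts %in% wanted
      if (!any(keep)) {
        warning("subset '", name, "' matches no loci; skipped")
        next
      }
      sub_am <- allele_matrix(am$locus_ids[keep], am$reference[keep],
                              am$calls[keep, , drop = FALSE],
                              am$coverage[keep, , drop = FALSE])
    }
    message("[phylo] subset ", name, ": ", length(sub_am$locus_ids), " loci")
    filtered <- filter_loci(sub_am, min_coverage = min_coverage)
    if (length(filtered$locus_ids) == 0) next
    d <- hamming_matrix(filtered)
    tree <- upgma(d)
    f_dist <- file.path(outdir, paste0("dist_", name, ".tsv"))
    write.table(data.frame(sample = rownames(d), signif(d, 6),
                           check.names = FALSE),
                f_dist, sep = "\t", quote = FALSE, row.names = FALSE)
    f_tree <- file.path(outdir, paste0("tree_", name, ".nwk"))
    writeLines(to_newick(tree), f_tree)
    outputs <- c(outputs, f_dist, f_tree)
    results[[name]] <- tree
  }
  manifest <- write_manifest(outdir, params,
                             inputs = list(loci = length(am$locus_ids),
                                           samples = am$sample_ids),
                             outputs = outputs)
  invisible(list(results = results, manifest = manifest))
}
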