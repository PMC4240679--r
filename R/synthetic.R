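#' Generate a two-condition count table with planted fold changes
#'
#' Baseline per-gene means are drawn log-normal (deliberately not negative
#' binomial, to avoid matching the parametric assumption of any particular DE
#' model). Planted genes alternate up/down regulation so that the DE signal
#' is globally unbiased; condition-b means multiply (or divide) the baseline
#' by `fold`. Per-sample counts are one multinomial draw of `library_size`
#' reads with probabilities proportional to the condition means.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_de number of planted DE genes (<= n_genes).
#' @param fold fold change of planted genes (> 0; 1 plants a null "change").
#' @param library_size reads per sample.
#' @param K_replicates replicates per condition.
#' @param seed RNG seed; output is reproducible from it.
#' @param meanlog,sdlog log-normal baseline parameters.
#' @param conditions labels for the two conditions (control first).
#' @return list with `table` (a [count_table()]), `design` (an
#'   [experiment_design()] with the single comparison control vs stress) and
#'   `truth` (data frame: gene, baseline, fold, log2fc, is_de, direction).
#' @export
generate_two_condition_counts <- function(n_genes = 5000, n_de = 50,
                                          fold = 8, library_size = 1e6,
                                          K_replicates = 1, seed = 1,
                                          meanlog = log(100), sdlog = 1.5,
                                          conditions = c("control", "stress")) {
  if (n_de > n_genes) stop("n_de must not exceed n_genes")
  if (fold <= 0) stop("fold must be positive")
  if (n_genes < 2 || library_size < 1 || K_replicates < 1)
    stop("invalid sizes")
  set.seed(seed %% 2147483647)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  baseline <- rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  de_idx <- sort(sample.int(n_genes, n_de))
  direction <- rep("none", n_genes)
  if (n_de > 0)
    direction[de_idx] <- rep_len(c("up", "down"), n_de)  # alternating
  gene_fold <- rep(1, n_genes)
  gene_fold[direction == "up"] <- fold
  gene_fold[direction == "down"] <- 1 / fold
  mean_b <- baseline * gene_fold

  draw <- function(means) as.integer(
    rmultinom(1, size = library_size, prob = means / sum(means))[, 1])
  counts <- matrix(0L, n_genes, 2 * K_replicates)
  sample_ids <- character(2 * K_replicates)
  cond_col <- character(2 * K_replicates)
  repl <- integer(2 * K_replicates)
  for (k in seq_len(K_replicates)) {
    counts[, k] <- draw(baseline)
    counts[, K_replicates + k] <- draw(mean_b)
    sample_ids[k] <- sprintf("%s_r%d", conditions[1], k)
    sample_ids[K_replicates + k] <- sprintf("%s_r%d", conditions[2], k)
    cond_col[k] <- conditions[1]; cond_col[K_replicates + k] <- conditions[2]
    repl[k] <- k; repl[K_replicates + k] <- k
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  truth <- data.frame(gene = gene_ids, baseline = baseline, fold = gene_fold,
                      log2fc = log2(gene_fold), is_de = direction != "none",
                      direction = direction, stringsAsFactors = FALSE)
  list(table = count_table(counts),
       design = experiment_design(sample_ids, cond_col, repl,
                                  comparisons = list(conditions)),
       truth = truth)
}

#' Default truth tree for allele-matrix simulations
#'
#' A fixed 6-leaf ultrametric tree of depth 1 with internal branches long
#' enough that a couple of thousand loci resolve every split.
#'
#' @return an `ape` phylo object.
#' @export
default_truth_tree <- function() {
  ape::read.tree(text = paste0(
    "((A:0.2,B:0.2):0.8,((C:0.5,D:0.5):0.3,(E:0.35,F:0.35):0.45):0.2);"))
}

#' Generate an allele-call matrix from a known tree
#'
#' Each locus starts from a random reference allele at the root and evolves
#' down the tree; on every branch the number of substitutions is Poisson with
#' mean `mutation_rate * branch length`, and each substitution replaces the
#' current allele by one of the other three nucleotides. Leaf alleles are
#' read off the tips; per-locus, per-sample read coverage is uniform over
#' `coverage_range`.
#'
#' @param tree ultrametric `phylo` tree with branch lengths (>= 3 leaves);
#'   defaults to [default_truth_tree()].
#' @param n_loci number of loci.
#' @param mutation_rate expected substitutions per locus per unit branch
#'   length.
#' @param coverage_range integer range (min, max) of simulated coverage.
#' @param seed RNG seed.
#' @param loci_per_transcript loci are grouped into synthetic transcripts of
#'   this size; locus ids are `transcript:position` with 0-based positions.
#' @return an object of class `allele_matrix` (see [read_allele_matrix()])
#'   with the generating tree attached as `truth_tree`.
#' @export
generate_allele_matrix <- function(tree = default_truth_tree(), n_loci = 2000,
                                   mutation_rate = 0.2,
                                   coverage_range = c(100, 200), seed = 1,
                                   loci_per_transcript = 100) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3) stop("tree must have at least 3 leaves")
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    stop("tree must have at least one positive branch length")
  set.seed(seed %% 2147483647)
  nt <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_loci)
  root <- n_tip + 1L
  states[root, ] <- sample.int(4, n_loci, replace = TRUE)
  tree_ord <- ape::reorder.phylo(tree, "cladewise")
  edge_mut <- integer(nrow(tree_ord$edge))
  for (e in seq_len(nrow(tree_ord$edge))) {
    parent <- tree_ord$edge[e, 1]; child <- tree_ord$edge[e, 2]
    len <- tree_ord$edge.length[e]
    hits <- rpois(n_loci, mutation_rate * len)
    st <- states[parent, ]
    for (locus in which(hits > 0)) {
      for (h in seq_len(hits[locus]))
        st[locus] <- sample(setdiff(1:4, st[locus]), 1)
    }
    states[child, ] <- st
    edge_mut[e] <- sum(st != states[parent, ])
  }
  calls <- matrix(nt[t(states[seq_len(n_tip), , drop = FALSE])],
                  nrow = n_loci, ncol = n_tip,
                  dimnames = list(NULL, tree$tip.label))
  coverage <- matrix(
    sample(seq(coverage_range[1], coverage_range[2]), n_loci * n_tip,
           replace = TRUE),
    nrow = n_loci, ncol = n_tip, dimnames = list(NULL, tree$tip.label))
  transcript <- sprintf("contig%05d",
                        ((seq_len(n_loci) - 1) %/% loci_per_transcript) + 1)
  pos <- (seq_len(n_loci) - 1) %% loci_per_transcript
  am <- allele_matrix(locus_ids = paste0(transcript, ":", pos),
                      reference = nt[states[root, ]],
                      calls = calls, coverage = coverage)
  am$truth_tree <- tree
  am$edge_substitutions <- edge_mut
  am
}
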