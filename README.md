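# rodeo

Non-parametric detection of differentially expressed (DE) and stable genes
from RNA-seq read counts, with an evaluation harness and a
comparative-exomics (allele-distance phylogeny) module.

## Who this is for

Transcriptomics studies of non-model organisms often have no reference
genome, few or no replicates, and libraries of very different depths —
settings where parametric DE tools (which assume a negative-binomial count
model and estimate its dispersion from replicates) are on thin ice. This
package takes a distribution-free route: it never models the counts, only
their relative structure.

## The method

For a sample with genes \(G\) and read counts \(c_g\), each gene's
expression is summarised by a **character function**
\(\phi_g \in \{1,\dots,P\}\): a scale-invariant map to one of \(P\) ordered
expression bins in which larger counts never get smaller bins and equal
counts share a bin. Its distribution under count noise is estimated by
simulation. Each of \(I\) iterations draws \(R\) reads multinomially with
probabilities \(p_g = \log(c_g+1)/\sum_j \log(c_j+1)\), orders genes by
decreasing assigned count, gives bin 1 to genes with no reads, and
least-squares-segments the cumulative ordered counts into \(P-1\) pieces
(first segment → bin \(P\), …, last → bin 2). Over iterations this yields a
per-gene histogram on the \(P\) bins.

Between two samples \(a, b\), genes are ranked by the **maximum norm**
distance

\[
\mathrm{dis}(\phi_g^a, \phi_g^b) \;=\; \max_x \bigl| C(\phi_g^a, x) - C(\phi_g^b, x) \bigr|,
\]

the Kolmogorov–Smirnov statistic on the cumulative bin histograms, with the
distance between histogram modes as tie-break. A gene is called DE when the
distance reaches \(\delta\) (1.0 by default) and the mode distance reaches
a threshold (5 at \(P = 15\)). **Stable** genes — active but unchanged —
are found per iteration as the longest increasing subsequence (LIS) of one
sample's expression ranks under the other's ordering, intersected across
iterations. A \(P \times P\) **dispersion** matrix (bin \(p\) in \(a\) vs
bin \(q\) in \(b\), aggregated over genes and iteration pairs) provides
over-/under-expression and neutrality diagnostics, the latter being the
recommended guide for choosing \(P\).

The package also ships a synthetic-data generator with planted fold
changes and known trees, a benchmarking harness (false-positive curves,
midrank ROC/AUC, top-x recovery, AUC-vs-threshold sweeps against
fold-change-labelled truth), and a comparative-exomics step that builds
average-linkage (UPGMA) dendrograms from pairwise allele Hamming distances
with Newick output.

## Worked example

```r
library(rodeo)

sim <- generate_two_condition_counts(n_genes = 2000, n_de = 30, fold = 8,
                                     library_size = 5e5, seed = 7)
params  <- rodeo_params(profile = "phalaris", seed = 7)   # P=15, I=100, R=auto
phi_ctl <- estimate_phi(sim$table, "control_r1", params)
phi_str <- estimate_phi(sim$table, "stress_r1", params)
records <- call_de(rank_genes(de_records(phi_ctl, phi_str)), params)
head(records)
#>     gene maxnorm mode_a mode_b mode_distance direction rank is_DE
#> 1 g00542       1      5     12             7        up    1  TRUE
#> 2 g00257       1      6     12             6        up    2  TRUE
#> 3 g00741       1      7     13             6        up    3  TRUE
#> 4 g00935       1      7     13             6        up    4  TRUE
#> 5 g01123       1     11      5             6      down    5  TRUE
#> 6 g01161       1      6     12             6        up    6  TRUE
```

Every top-ranked gene has max-norm distance 1 (its stress and control bin
histograms have disjoint cumulative support) and a mode shift of 6–7 bins;
`direction` is relative to the second (stress) sample. At these settings 14
genes are called DE — all of them truly planted (the remaining planted
genes fall below the strict mode-distance cut) — and the full ranking
separates planted from null genes with

```r
labels <- label_truth(data.frame(gene = sim$truth$gene, logfc = sim$truth$log2fc))
roc_auc(records$gene, labels, scores = de_scores(records))$auc
#> [1] 0.9793893
```

The pipeline wrappers `run_de()`, `run_stable()` and `run_phylo()` write
ranked tables, gene lists, dispersion diagnostics, Newick trees and a run
manifest under an output directory; `inst/cli/rodeo` exposes them as shell
subcommands (`simulate`, `de`, `stable`, `phylo`, `eval`).

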