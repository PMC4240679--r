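Package: rodeo
Title: Non-Parametric Differential and Stable Gene Detection from RNA-Seq Read Counts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rank-based detection of differentially expressed and stable genes
    from RNA-seq read counts, without distributional assumptions on the counts.
    Per-gene expression is summarised by a scale-invariant character function:
    reads are repeatedly reassigned to genes by multinomial resampling, the
    cumulative ordered counts are segmented into P expression bins by
    least-squares linear segmentation, and each gene accumulates an empirical
    histogram over bins. Genes are ranked between two samples by the maximum
    norm (Kolmogorov-Smirnov type) distance between their cumulative bin
    histograms, with mode distance as tie-break; stable genes are found as
    longest increasing subsequences of per-iteration expression rankings,
    intersected over iterations. Includes dispersion/neutrality diagnostics,
    a synthetic-data generator with planted fold changes, an evaluation
    harness (false-positive curves, ROC/AUC, top-x recovery), and a
    comparative-exomics module (allele Hamming distances, UPGMA dendrograms,
    Newick export).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
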