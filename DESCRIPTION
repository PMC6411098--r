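Package: ca20
Title: Centrosome Amplification Signature Scoring and Pan-Cancer
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes the CA20 centrosome-amplification metagene score from
    bulk expression cohorts (voom-style log-CPM, quantile normalization,
    across-sample median centering, signature sum) and provides the
    downstream analysis toolkit built around it: Wilcoxon / Spearman /
    multiple-regression association scans against clinical and
    genomic-instability features, chromosome-arm and mutation volcano
    scans with Benjamini-Hochberg control, preranked gene-set enrichment
    with gene-label permutation p-values, median-split Kaplan-Meier
    survival stratification with log-rank testing, drug-sensitivity and
    perturbation-connectivity integration for candidate-compound
    discovery, and per-patient centriole-count summaries. A seeded
    synthetic multi-omic cohort and cell-line panel generator emulates the
    statistical structure these analyses assume, so every stage is
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    stats,
    survival,
    utils
Suggests:
    car,
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
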