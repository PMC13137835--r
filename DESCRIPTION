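Package: txconcord
Title: Transcriptomic Convergence and Divergence Analysis for Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies how faithfully an in vitro disease model reproduces a
    reference disease transcriptome. Provides an in-house negative-binomial
    differential expression engine (median-of-ratios normalization,
    method-of-moments dispersion estimation with trend shrinkage, per-gene
    Wald tests, Benjamini-Hochberg adjustment), gene-level
    convergent/divergent classification of model contrasts against a
    reference disease contrast with exclusion-set logic, hypergeometric
    over-representation analysis and permutation-based gene set enrichment
    analysis over GMT collections, a negative-binomial count simulator with
    planted differential expression and planted concordance structure, and a
    config-driven pipeline with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
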