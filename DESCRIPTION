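Package: trailkit
Title: Enrichment Analysis Workflows for Epigenomic, Time-Series and
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A library and command-line toolkit for high-throughput
    enrichment analysis. Implements over-representation analysis
    (hypergeometric test), an unweighted running-sum (GSEA-style) set
    enrichment statistic with permutation p-values, and multiple-testing
    correction, together with three workflows built on this engine:
    chromatin-state transition enrichment from histone-mark BED tracks,
    two-stage hierarchical clustering of time-resolved expression data
    with per-cluster enrichment, and per-cell enrichment of single-cell
    RNA-seq data with chi-square characterization of cell groups.
    Deterministic synthetic-fixture generators with known ground truth
    are included for every workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    graphics,
    grDevices,
    Matrix,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
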