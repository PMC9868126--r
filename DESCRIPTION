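Package: fosnet
Title: Whole-Brain c-Fos Activation and Functional-Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for whole-brain c-Fos cell-count tables from
    cleared-brain imaging: region hierarchies with volumes and exclusion
    handling, count-to-density conversion, per-region differential activation
    by negative-binomial regression with Dunnett and Benjamini-Hochberg
    multiplicity control, fold indices, per-group interregional Pearson
    correlation matrices, hierarchical-clustering modularity curves compared
    by the log-rank (Mantel-Cox) statistic, and thresholded functional-network
    graphs with hub ranking. Also provides silent-synapse estimation from
    minimal-stimulation recordings, NMDAR current decay-time fitting,
    locomotor path-length and two-bottle preference metrics, and a
    synthetic-cohort generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
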