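Package: smashsvg
Title: Kernel-Based Detection of Spatially Variable Genes in Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Non-parametric kernel association tests for detecting
    spatially variable genes (SVGs) in spatial transcriptomics data. The
    core test (SMASH) measures dependence between a gene's expression
    vector and spatial location through the trace of the product of an
    expression Gram matrix and a spatial kernel covariance matrix
    (Gaussian, cosine/periodic, or linear-projection families), with a
    moment-matched gamma approximation to the quadratic-form null
    distribution. The linear-projection special case reproduces the
    SPARK-X score test. Includes data readers for Matrix Market and
    delimited tables, covariate residualization, data-driven kernel
    hyperparameter grids, Benjamini-Yekutieli FDR control, negative
    binomial and Gaussian-process simulators of spatial expression, and
    evaluation utilities (power, type-I error, QQ calibration, marker-set
    enrichment scores).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
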