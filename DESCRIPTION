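Package: cortexdev
Title: Developmental Cell-Type Analysis of Cortical Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative single-nucleus RNA-seq analysis of
    developing sensory cortex. Implements multi-round quality control and
    cluster purification, subclass-variability and temporal
    differential-expression (SV/tDE) quadrant scoring of gene regulation,
    gene-category enrichment, subclass-wise differential expression and
    exclusive set intersections, gradient-boosted cell-type label transfer
    with a probability-rejection rule, marker-based PCA analysis of the
    layer 2/3 cell-type continuum, and hypergeometric overlap statistics
    between regions. A negative-binomial synthetic-data generator with
    planted ground truth (subclass markers, temporal programs, a three-type
    continuum with a compositional shift, doublet and low-quality artifacts)
    backs every stage with a known answer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    xgboost,
    jsonlite,
    yaml,
    withr,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
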