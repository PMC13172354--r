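Package: trajdyn
Title: Trajectory-Constrained Gene Dynamics, Fiber Alignment and Skin
    Viscoelasticity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene expression dynamics along a
    pseudotime trajectory in single-cell RNA-seq data: principal-graph path
    extraction, distance-percentile cell selection, LOESS modelling of
    expression against pseudotime, a dynamics-range score separating static
    from dynamic genes, and Spearman-correlation ranking of fate-determining
    genes. Also provides cell-level quality-control filtering and total-count
    log-normalization, two-dimensional FFT radial summation for quantifying
    anisotropic fiber and vessel alignment in micrographs, and Cutometer-style
    suction-curve viscoelasticity ratios (R2, R7). A synthetic-data module
    generates trajectories with known dynamic genes, oriented-fiber images and
    parametric suction curves so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
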