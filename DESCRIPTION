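Package: gcconnect
Title: Effective and Functional Brain Connectivity from ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates directed effective connectivity between regional
    fMRI time series by nonlinear conditional Granger causality, using a
    stack of small adaptive-kernel convolution predictors trained per
    region pair, with K-fold edge significance testing at group and
    individual level. Computes undirected functional connectivity as
    conditional partial Pearson correlation with significance-thresholded
    edges and group consensus graphs. Provides a battery of ten global
    graph metrics with directed and undirected variants (degree, strength,
    clustering, transitivity, modularity, global efficiency,
    characteristic path length, in-out assortativity, small-worldness,
    flow coefficient), covariate-adjusted linear association screens of
    metrics against participant characteristics, and a synthetic cohort
    generator with known planted causal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
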