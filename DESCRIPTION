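Package: flyrisk
Title: Invasion Risk Mapping for the Peach Fruit Fly via Presence-Background
    Niche Modelling and Gaussian Dispersal Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for mapping the invasion risk of the
    peach fruit fly Bactrocera zonata (and similar presence-only invasive
    taxa). Cleans and spatially thins occurrence records, prunes collinear
    bioclimatic predictors by pairwise Pearson correlation, fits an
    L1-regularised maximum-entropy (MaxEnt-style) climatic-suitability model
    with linear, quadratic and hinge features, merges climatic suitability
    with host-plant availability into an overall habitat-suitability surface,
    and models short-distance natural spread from known source locations with
    a Gaussian dispersal kernel. Ships a synthetic-data generator that
    produces spatially autocorrelated predictor stacks with controlled
    collinearity, a known true-suitability surface, presence samples and host
    rasters, so the whole pipeline is testable end to end without external
    downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret
Config/testthat/edition: 3
RoxygenNote: 7.3.3
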