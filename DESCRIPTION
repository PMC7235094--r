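Package: tripuncta
Title: Quantitative Analysis of Tripartite Synapse Nanostructure in
    Punctate Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying excitatory (tripartite)
    synapse organisation in single-plane fluorescence images of nervous
    tissue. Implements punctum segmentation (rolling-ball background
    subtraction, Gaussian smoothing, moment-preserving and minimum
    cross-entropy auto-thresholding, connected-component particle
    detection with raw-intensity measurement), the postsynaptic density
    (PSD) to nanocluster hierarchy from paired confocal/STED
    segmentations, full-width-at-half-maximum line-profile sizing of
    nanostructures, object-overlap colocalization with a four-way
    tripartite categorisation, nearest-neighbour and edge-edge distance
    statistics with a 180-degree rotated spatial null, laminar region
    mapping with per-animal aggregation, and a Pearson contingency
    chi-squared test. A ground-truth synthetic scene generator renders
    two-resolution noisy channels so that every stage is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
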