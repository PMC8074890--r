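Package: soilpore
Title: Surrogate-Annotation Deep Learning for Soil-Core CT Porosity Profiles
Version: 0.1.0
Authors@R:
    person("Soil Structure Analytics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for structural analysis of X-ray computed tomography scans
    of cylindrical soil cores. The Hounsfield-unit range is partitioned into
    object-class bands (organic matter, soil matrix, stones, ...), volumes are
    binarized per band, small clusters are trimmed, and per-slice porosity
    profiles along the core axis are computed. These profiles serve as
    surrogate annotations to train a VGG-style convolutional regression
    network on band-stacked slice images, including transfer learning with a
    frozen convolutional stack, cross-model compatibility screening via an
    RMSE matrix with greedy representative selection, and grad-CAM heatmaps
    for model verification. A seeded synthetic soil-core generator with exact
    voxel-level material labels makes the whole pipeline testable without any
    real scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
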