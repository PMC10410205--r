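Package: sealspacing
Title: Fine-Scale Spacing Analysis of Seal Haul-Out Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spatial analysis of georeferenced seal-outline polygons from
    aerial imagery of haul-out colonies. Computes edge-to-edge
    nearest-neighbour distances and fixed-radius neighbourhood densities per
    animal, compares species (grey seal, harbour seal) with quantile
    regression and negative-binomial models, and tests for avoidance at
    small distances ("social distancing") against a kernel-intensity-based
    spatial-perturbation null model that displaces each animal while
    preserving its orientation and resolving polygon overlaps by incremental
    rotation and translation. Includes a synthetic-colony generator with
    controllable clustering and hard-core spacing so the full pipeline can be
    exercised without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    polyclip,
    quantreg,
    Rcpp,
    graphics,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    sp,
    spatstat.explore,
    spatstat.geom,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
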