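Package: odftoolbox
Title: In Vitro Characterisation Toolbox for Orodispersible Films
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis toolbox for in vitro characterisation of
    orodispersible films (ODFs). Provides a ground-truth-scripted synthetic
    scenario generator (plan-view disintegration videos, reciprocating-sled
    friction traces, shear-thinning flow curves, simulated Petri-dish
    observations), a video disintegration profiler (dye-based segmentation,
    fragment tracking, persistent-split endpoint detection with right
    censoring at the 180 s Pharmacopoeial cap), stroke-wise coefficient of
    friction analysis with piecewise-constant change-point endpoint
    detection, rheological flow-curve model fitting (power-law and Cross),
    and an orchestration layer that reproduces cross-method disintegration
    summaries with censoring notation and group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
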