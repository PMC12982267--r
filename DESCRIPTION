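Package: pollinet
Title: Species-Based Urban Pollinator Connectivity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for assessing multi-species habitat
    connectivity for insect pollinators in urban landscapes. Builds
    habitat-suitability surfaces from occurrence records and land-cover
    predictors using penalized additive logistic models with double-penalty
    shrinkage, converts combined suitability into a movement-resistance
    surface, computes circuit-theory current maps and effective resistances
    between core habitat areas, extracts least-cost corridors and
    pinch-point clusters, and performs a gap analysis against an
    independently supplied planner corridor network. Includes a synthetic
    landscape and occurrence generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    sp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    MASS,
    withr
Config/testthat/edition: 3
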