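Package: lucesv
Title: Land-Use Change Simulation and Ecosystem Service Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts land-use demand with GM(1,1) grey prediction and
    Markov transition-matrix models, allocates the demanded class areas on
    a raster with a constrained cellular automaton (neural-network
    suitability surfaces, adaptive inertia, conversion rules, restricted
    zones, roulette selection), and values the resulting landscapes with a
    regionally corrected equivalent-factor ecosystem-service model.
    Includes a seeded synthetic-landscape generator so the whole pipeline
    runs and is testable without external raster data, plus accuracy
    assessment (confusion matrix, kappa) and plain-text raster and table
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
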