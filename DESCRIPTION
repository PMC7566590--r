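Package: odmodels
Title: Spatial Interaction Models for Origin-Destination Flows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits and compares spatial interaction models on
    origin-destination count data. Implements the production-constrained
    gravity model with power-law or exponential deterrence and a family of
    radiation models (original and normalised forms, with eight mappings of
    site data to model parameters), evaluated by Poisson regression:
    truncated log-likelihood, BIC, deviance, and Hessian-based standard
    errors for fitted global parameters. Includes legacy comparison metrics
    (Sorensen-Dice overlap and R squared), a seeded generator of synthetic
    commuter-flow systems for testing and parameter-recovery studies, and a
    command-line interface for batch model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
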