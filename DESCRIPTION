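Package: nichecast
Title: Presence-Background Maximum-Entropy Niche Modelling and Habitat Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end species distribution modelling toolkit built
    around a presence-background maximum-entropy (MaxEnt-type) engine with
    L1-regularized coordinate-descent fitting over linear, quadratic,
    product, hinge and threshold features. Supports AICc-based tuning over
    regularization-multiplier and feature-class grids, variable screening
    (zero-contribution drop and Pearson collinearity pruning), four-level
    habitat-suitability classification with area dynamics under climate
    scenarios, Schoener's D and Levins niche breadth metrics, protected-area
    gap analysis, and range-centroid shift tracking. Includes a synthetic
    environmental-world generator so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
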