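Package: monarchthreats
Title: Threat Attribution for the Eastern Monarch Butterfly Overwintering
    Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage threat-attribution analysis for annual indices of
    the eastern migratory monarch butterfly (Danaus plexippus) overwintering
    population. Provides a synthetic-data generator emulating a short annual
    time series with many correlated environmental covariates, iterative
    SVD (DINEOF) imputation of missing covariate cells with cross-validated
    rank selection, univariate NIPALS partial least-squares regression with
    leave-one-out PRESS/Q2 and loading-based variable selection, exhaustive
    best-subset Gompertz time-series regression ranked by BIC with model
    weights, variable importance and shrinkage model averaging, and a
    recursive three-variable structural path model (herbicide to milkweed
    to population) with chi-square, RMSEA and CFI fit indices. Also includes
    insect degree-day covariate engineering (growing and lethal degree days)
    and annualization of multi-year habitat-loss totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    nlme,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
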