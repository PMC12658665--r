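Package: fireits
Title: Two-Stage Interrupted Time Series for Excess Acute Care Visits
    After Environmental Disasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates excess outpatient and virtual acute-care visits after an
    abrupt environmental disaster (such as an urban wildfire) with a two-stage
    interrupted time-series design. Stage one fits a hybrid counterfactual model
    (structural seasonal-trend regression plus a gradient-boosted residual
    corrector on meteorological and surveillance covariates) on pre-event data,
    selecting hyperparameters by root-mean-square error across rolling-origin
    cross-validation folds. Stage two computes daily and cumulative excess
    visits with 95% empirical confidence intervals from a moving-block
    bootstrap of pre-period residuals over 1000 Monte Carlo iterations.
    Includes distance-buffer exposure zoning of census tracts against burn-zone
    polygons, ICD-10 range classification into cause categories, market-share
    extrapolation to an insured population, and a synthetic daily-visit
    generator with known injected effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    ggplot2,
    jsonlite,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
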