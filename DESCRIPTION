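Package: mortmcs
Title: Stochastic Mortality Model Pools, Model Confidence Sets and
    Forecast Combination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a pool of stochastic mortality models -- the Poisson
    generalized age-period-cohort family (Lee-Carter, Renshaw-Haberman,
    age-period-cohort, Cairns-Blake-Dowd, M6, M7, M8, Plat), SVD-based
    Lee-Carter variants with period-index adjustments, and functional
    time-series models (functional data model, robust variant,
    product-ratio, multivariate and multilevel decompositions) -- to
    age-by-year mortality surfaces, produces point and interval
    forecasts, scores them out of sample by root mean squared forecast
    error and mean interval score in an expanding-window design, trims
    the pool with the model confidence set procedure of equal predictive
    ability tests under a moving-block bootstrap, and combines forecasts
    from the surviving superior set with equal weights, with an
    inverse-validation-error weighting scheme as a baseline.  Includes a
    synthetic mortality-surface generator with known ground truth and
    readers for Human Mortality Database style rate tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
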