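Package: synbeats
Title: Ensemble N-BEATS Forecasting for Hourly Air-Pollutant Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting hourly pollutant concentrations (NO, NO2,
    NOx, O3, PM2.5) from a single monitoring station under data-limited
    conditions. Implements the N-BEATS basis-expansion architecture (blocks
    emitting a backcast and a forecast, chained through residuals within and
    across stacks) from scratch, and the syN-BEATS ensemble: a family of
    N-BEATS models whose stacks-times-blocks products share one block budget,
    combined by a weighted linear sum. Ensemble weights are either predefined
    from inverse-squared relative RMSE on an inner validation split, or tuned
    by Bayesian optimization with a Gaussian-process surrogate and
    expected-improvement acquisition. Includes hourly CSV ingestion with Akima
    gap filling, chronological splitting, sliding-window construction,
    RMSE/RRMSE evaluation, a synthetic two-regime data generator for testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
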