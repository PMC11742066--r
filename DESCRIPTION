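Package: hawksvr
Title: Harris Hawks Optimization of Support Vector Regression for PM2.5
    Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Hybrid metaheuristic forecasting of daily fine particulate
    matter (PM2.5) concentrations. Implements Harris Hawks Optimization
    (HHO) over bounded continuous spaces, an epsilon-insensitive support
    vector regression (SVR) with Gaussian radial basis kernel trained by a
    sequential minimal optimization dual solver, and the coupling of the
    two: HHO tunes the SVR cost and kernel width against a k-fold
    cross-validated mean absolute percentage error objective. Ships the
    surrounding evaluation protocol (multi-run best/worst/average/spread
    summaries, Friedman rank test for algorithm comparison), a reader for
    the CDC/EPA Downscaler daily county-level PM2.5 table format, and
    seed-deterministic synthetic-data generators for PM2.5-like series,
    SVR-recoverable regression testbeds and analytic benchmark objectives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
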