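# Download-free generators: PM2.5-like daily series, SVR-recoverable
# regression testbeds, and analytic benchmark objectives. All are pure
# functions of their specification and seed.

#' Specification of a synthetic PM2.5-like series
#'
#' Defaults match the published descriptive profile of county 1001's
#' daily maximum series: mean ~12.1 ug/m3, SD ~5.1, skewness ~1.4,
#' strictly positive support, mild day-to-day autocorrelation and annual
#' seasonality.
#'
#' @param n Series length in days. Default 3500.
#' @param target_mean,target_sd Calibration targets in ug/m3.
#' @param target_skewness Target marginal skewness (> 0; the lognormal
#'   family only produces right skew).
#' @param ar_coef Lag-1 autocorrelation of the latent Gaussian process,
#'   in \[0, 0.99\].
#' @param seasonal_amp Amplitude of the annual sinusoid, ug/m3.
#' @param period Season length in days. Default 365.
#' @param seed RNG seed.
#' @return A `series_spec` object.
#' @export
series_spec <- function(n = 3500, target_mean = 12.12, target_sd = 5.07,
                        target_skewness = 1.38, ar_coef = 0.6,
                        seasonal_amp = 2, period = 365, seed = 1) {
  n <- check_count(n, "n", 10L)
  check_number(target_mean, "target_mean", 0, strict = TRUE)
  check_number(target_sd, "target_sd", 0, strict = TRUE)
  check_number(target_skewness, "target_skewness", 0, strict = TRUE)
  check_number(ar_coef, "ar_coef", 0)
  if (ar_coef > 0.99) abort("`ar_coef` must be <= 0.99.")
  check_number(seasonal_amp, "seasonal_amp", 0)
  period <- check_count(period, "period", 2L)
  if (seasonal_amp^2 / 2 >= target_sd^2) {
    abort("infeasible spec: seasonal amplitude exceeds the target SD.")
  }
  structure(list(n = n, target_mean = target_mean, target_sd = target_sd,
                 target_skewness = target_skewness, ar_coef = ar_coef,
                 seasonal_amp = seasonal_amp, period = period, seed = seed),
            class = "series_spec")
}

# latent log-scale SD that gives a lognormal the target skewness
lognormal_sigma_for_skewness <- function(skew) {
  f <- function(w) (w + 2) * sqrt(w - 1) - skew
  w <- stats::uniroot(f, c(1 + 1e-12, 10))$root
  sqrt(log(w))
}

#' Generate a synthetic PM2.5-like daily series
#'
#' An exponentiated Gaussian AR(1) (positive, right-skewed, mildly
#' autocorrelated) plus an annual cosine peaking in winter, affinely
#' calibrated so the sample mean and SD approach the targets. Skewness
#' is emergent from the lognormal family rather than calibrated exactly.
#' The output is strictly positive; a specification whose calibration
#' would cross zero is rejected.
#'
#' @param spec A [series_spec()].
#' @return A tibble with `date` (daily from 2001-01-01) and `pm25`
#'   (ug/m3, all positive). Deterministic given `spec$seed`.
#' @export
gen_pm25_series <- function(spec = series_spec()) {
  stopifnot(inherits(spec, "series_spec"))
  set.seed(spec$seed)
  n <- spec$n
  sig_g <- lognormal_sigma_for_skewness(spec$target_skewness)
  phi <- spec$ar_coef
  innov_sd <- sig_g * sqrt(1 - phi^2)
  g <- numeric(n)
  g[1] <- rnorm(1, 0, sig_g)
  for (t in seq_len(n)[-1]) g[t] <- phi * g[t - 1] + rnorm(1, 0, innov_sd)
  base <- exp(g)
  day <- seq_len(n)
  seasonal <- spec$seasonal_amp * cos(2 * pi * (day - 15) / spec$period)
  resid_sd2 <- spec$target_sd^2 - var(seasonal)
  if (resid_sd2 <= 0) abort("infeasible spec: no variance left for the AR component.")
  b <- sqrt(resid_sd2) / sd(base)
  a <- spec$target_mean - b * mean(base) - mean(seasonal)
  pm25 <- a + b * base + seasonal
  if (min(pm25) <= 0) {
    abort("infeasible spec: calibrated series is not strictly positive.")
  }
  tibble(date = as.Date("2001-01-01") + day - 1L, pm25 = pm25)
}

#' Format a synthetic series as a Downscaler-style table
#'
#' Emits the daily county-level CSV schema (state/county FIPS, year,
#' day-month-year date, four concentration columns) for a single
#' synthetic county. All four concentration columns carry the same
#' synthetic value.
#'
#' @param series Tibble with `date` and `pm25` from [gen_pm25_series()].
#' @param statefips,countyfips FIPS codes for the synthetic county.
#' @return A tibble in the 8-column table layout.
#' @export
as_cdc_table <- function(series, statefips = 1, countyfips = 1) {
  tibble(
    STATEFIPS = statefips, COUNTYFIPS = countyfips,
    YEAR = as.integer(format(series$date, "%Y")),
    DATE = format(series$date, "%d-%m-%Y"),
    `PM2.5-MAX-PRED` = series$pm25, `PM2.5-MED-PRED` = series$pm25,
    `PM2.5-MEAN-PRED` = series$pm25, `PM2.5-POP-PRED` = series$pm25
  )
}

#' Generate an SVR-recoverable regression testbed
#'
#' Targets are a smooth positive function of two features (a constant
#' plus two Gaussian bumps, exactly representable by an RBF expansion)
#' corrupted with Gaussian noise. The noiseless generating function is
#' returned so error floors can be computed.
#'
#' @param n Number of samples (>= 50).
#' @param noise_sd Gaussian noise SD on the targets. Default 0.05.
#' @param seed RNG seed.
#' @return A list with `data` (tibble `x1`, `x2`, `target`), `oracle`
#'   (function of an n x 2 matrix returning the noiseless targets), and
#'   `noise_sd`.
#' @export
gen_svr_recoverable <- function(n = 300, noise_sd = 0.05, seed = 1) {
  n <- check_count(n, "n", 50L)
  check_number(noise_sd, "noise_sd", 0)
  set.seed(seed)
  oracle <- function(x) {
    x <- as.matrix(x)
    2 + 1.5 * exp(-((x[, 1] - 3)^2 + (x[, 2] - 7)^2) / (2 * 2^2)) +
      1.2 * exp(-((x[, 1] - 8)^2 + (x[, 2] - 2)^2) / (2 * 2.5^2))
  }
  x <- matrix(runif(n * 2, 0, 10), n, 2)
  y <- oracle(x) + rnorm(n, 0, noise_sd)
  list(
    data = tibble(x1 = x[, 1], x2 = x[, 2], target = y),
    oracle = oracle,
    noise_sd = noise_sd,
    seed = seed
  )
}

#' Analytic benchmark objectives
#'
#' Standard test functions with known minimizer and minimum 0, for
#' exercising optimizers: the sphere, a shifted quadratic, and the 2-D
#' Rosenbrock valley.
#'
#' @return A named list; each entry has `fn`, `minimizer`, `minimum` and
#'   a default `space`.
#' @export
benchmark_objectives <- function() {
  list(
    sphere = list(
      fn = function(x) sum(x^2),
      minimizer = c(0, 0), minimum = 0,
      space = search_space(-10, 10, dim = 2)
    ),
    shifted_quadratic = list(
      fn = function(x) sum((x - c(2, -3))^2),
      minimizer = c(2, -3), minimum = 0,
      space = search_space(-10, 10, dim = 2)
    ),
    rosenbrock = list(
      fn = function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2,
      minimizer = c(1, 1), minimum = 0,
      space = search_space(-5, 10, dim = 2)
    )
  )
}
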