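# CDC/Downscaler table reader, series selection, descriptive statistics,
# and report serialization.

make_fixture_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- "STATEFIPS,COUNTYFIPS,YEAR,DATE,PM2.5-MAX-PRED,PM2.5-MED-PRED,PM2.5-MEAN-PRED,PM2.5-POP-PRED"
  writeLines(c(header, rows), path)
  path
}

good_rows <- c(
  "1,1001,2001,01-01-2001,12.5,10.1,10.8,10.9",
  "1,1001,2001,02-01-2001,14.2,11.3,11.9,12.0",
  "1,1003,2001,01-01-2001,9.7,8.2,8.5,8.6"
)

test_that("well-formed files parse completely", {
  rec <- read_cdc_pm25(make_fixture_csv(good_rows))
  expect_equal(nrow(rec), 3)
  expect_equal(nrow(attr(rec, "rejects")), 0)
  expect_equal(attr(rec, "date_format"), "%d-%m-%Y")
  expect_equal(rec$pm25_max_pred, c(12.5, 14.2, 9.7))
  expect_equal(rec$date[2], as.Date("2001-01-02"))
})

test_that("malformed rows are rejected with row numbers, not dropped silently", {
  rows <- c(good_rows[1], "1,1001,2001,03-01-2001,oops,11,11,11", good_rows[3])
  rec <- read_cdc_pm25(make_fixture_csv(rows))
  expect_equal(nrow(rec), 2)
  rej <- attr(rec, "rejects")
  expect_equal(rej$row, 2)
  expect_match(rej$reason, "concentration")
  # negative concentrations are also invalid
  rows2 <- c(good_rows[1], "1,1001,2001,03-01-2001,-4,11,11,11")
  expect_equal(attr(read_cdc_pm25(make_fixture_csv(rows2)), "rejects")$row, 2)
  # year/date mismatch
  rows3 <- c(good_rows[1], "1,1001,2005,03-01-2001,10,11,11,11")
  expect_match(attr(read_cdc_pm25(make_fixture_csv(rows3)), "rejects")$reason,
               "year")
})

test_that("missing mandatory columns are named in the error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("STATEFIPS,COUNTYFIPS,YEAR,DATE", "1,1,2001,01-01-2001"), path)
  expect_error(read_cdc_pm25(path), "pm25_max_pred")
})

test_that("write + read round-trips a synthetic table bit-exactly", {
  s <- gen_pm25_series(series_spec(n = 50, seed = 7))
  tab <- as_cdc_table(s, statefips = 1, countyfips = 1001)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  rec <- read_cdc_pm25(path)
  expect_equal(nrow(rec), 50)
  expect_identical(rec$pm25_max_pred, s$pm25)
  expect_identical(rec$date, s$date)
})

test_that("series selection sorts, filters and rejects duplicates", {
  rec <- read_cdc_pm25(make_fixture_csv(good_rows[c(2, 1, 3)]))  # shuffled
  ser <- select_series(rec, 1001, "pm25_max_pred")
  expect_equal(ser$value, c(12.5, 14.2))
  expect_true(!is.unsorted(ser$date))
  expect_error(select_series(rec, 9999), "no records")
  expect_error(select_series(rec, 1001, "not_a_column"), "variable")
  dup <- read_cdc_pm25(make_fixture_csv(good_rows[c(1, 1)]))
  expect_error(select_series(dup, 1001), "duplicate dates")
})

test_that("series selection matches a linear-scan oracle", {
  s <- gen_pm25_series(series_spec(n = 100, seed = 8))
  tab <- dplyr::bind_rows(
    as_cdc_table(s[1:60, ], countyfips = 1001),
    as_cdc_table(s[61:100, ], countyfips = 1003)
  )
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tab[sample(nrow(tab)), ], path)
  rec <- read_cdc_pm25(path)
  ser <- select_series(rec, 1003, "pm25_med_pred")
  oracle_rows <- tab[tab$COUNTYFIPS == 1003, ]
  oracle_vals <- oracle_rows$`PM2.5-MED-PRED`[order(as.Date(oracle_rows$DATE, "%d-%m-%Y"))]
  expect_equal(ser$value, oracle_vals)
  expect_equal(nrow(ser), 40)
})

test_that("descriptive statistics match hand arithmetic and invariants", {
  d <- descriptive_stats(c(1, 2, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  expect_equal(d$mode, 2)
  expect_equal(d$sample_variance, 2 / 3)
  expect_equal(descriptive_stats(c(-1, 0, 1))$skewness, 0)
  # mode ties resolve to the smallest value
  expect_equal(descriptive_stats(c(5, 5, 2, 2, 9))$mode, 2)
  set.seed(12)
  for (i in 1:3) {
    x <- rlnorm(200, 2, 0.4)
    d <- descriptive_stats(x)
    expect_equal(d$range, d$maximum - d$minimum)
    expect_equal(d$standard_error, d$standard_deviation / sqrt(d$count))
    expect_equal(d$sample_variance, d$standard_deviation^2)
    expect_equal(d$sum, sum(x))
    expect_equal(d$count, 200)
  }
  expect_error(descriptive_stats(3), "at least 2")
})

test_that("skewness and kurtosis follow the bias-corrected convention", {
  set.seed(13)
  x <- rlnorm(150, 1, 0.5)
  d <- descriptive_stats(x)
  expect_equal(d$skewness, e1071::skewness(x, type = 2))
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 2))
})

test_that("reports serialize to json and csv and read back", {
  g <- gen_svr_recoverable(n = 80, noise_sd = 0.05, seed = 9)
  cfg <- tuning_config(n_agents = 3, max_iter = 2, runs = 2, k_folds = 4)
  rep <- run_experiment(g$data, cfg, master_seed = 3)

  jpath <- tempfile(fileext = ".json")
  write_report(rep, jpath, "json")
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$best, rep$best)
  expect_equal(back$C, rep$best_C)

  cpath <- tempfile(fileext = ".csv")
  write_report(rep, cpath, "csv")
  csv <- readr::read_csv(cpath, show_col_types = FALSE)
  expect_equal(names(csv), c("Best", "Worst", "Average", "SD", "CPU Time",
                             "C", "Alpha"))
  expect_equal(csv$Alpha, rep$best_sigma)

  fr <- friedman_test(as.matrix(mape_run_table(1001)[-1]))
  fpath <- tempfile(fileext = ".json")
  write_report(fr, fpath, "json")
  fback <- jsonlite::read_json(fpath, simplifyVector = TRUE)
  expect_equal(fback$chi_square, fr$chi_square)
  expect_equal(fback$mean_ranks$HHO, unname(fr$mean_ranks["HHO"]))

  expect_error(write_report(list(1), tempfile()), "unsupported")
})
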