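# Reader for the CDC/EPA Downscaler daily county-level PM2.5 CSV schema,
# series selection, descriptive statistics, and report writing.

# canonical column names and the header aliases they match after
# stripping case and punctuation
cdc_canonical <- c(
  statefips = "statefips", countyfips = "countyfips", year = "year",
  date = "date",
  pm25maxpred = "pm25_max_pred", pm25medpred = "pm25_med_pred",
  pm25meanpred = "pm25_mean_pred", pm25poppred = "pm25_pop_pred"
)

normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(gsub("2\\.5", "25", x)))

pm25_columns <- c("pm25_max_pred", "pm25_med_pred", "pm25_mean_pred",
                  "pm25_pop_pred")

# candidate date dialects tried during auto-detection, day-month-year first
date_formats <- c("%d-%m-%Y", "%Y-%m-%d", "%m/%d/%Y", "%d/%m/%Y", "%d-%b-%Y")

detect_date_format <- function(dates) {
  hits <- vapply(date_formats,
                 function(f) sum(!is.na(as.Date(dates, format = f))),
                 numeric(1))
  if (max(hits) == 0) return(NA_character_)
  date_formats[which.max(hits)]
}

#' Read a daily county-level PM2.5 table
#'
#' Parses the Downscaler CSV schema (state/county FIPS, year, date, and
#' the four daily PM2.5 prediction columns: maximum, median, mean and
#' population-weighted, all in micrograms per cubic metre). Header names
#' are matched case- and punctuation-insensitively. Malformed rows (bad
#' date, non-numeric or negative concentration, year/date mismatch) are
#' collected into a rejects table attached as an attribute, never
#' silently dropped.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param date_format Optional `strptime` format for the `DATE` column;
#'   by default day-month-year is tried first, then common alternatives,
#'   keeping whichever parses the most rows.
#' @return A tibble of clean records (`statefips`, `countyfips`, `year`,
#'   `date`, `pm25_max_pred`, `pm25_med_pred`, `pm25_mean_pred`,
#'   `pm25_pop_pred`) with attributes `rejects` (tibble of `row`,
#'   `reason`) and `date_format`.
#' @export
read_cdc_pm25 <- function(path, date_format = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  key <- normalize_header(names(raw))
  missing <- setdiff(names(cdc_canonical), key)
  if (length(missing) > 0) {
    abort(sprintf("missing mandatory columns: %s.",
                  paste(cdc_canonical[missing], collapse = ", ")))
  }
  raw <- raw[match(names(cdc_canonical), key)]
  names(raw) <- unname(cdc_canonical)

  if (is.null(date_format)) date_format <- detect_date_format(raw$date)
  if (is.na(date_format)) abort("could not detect a date format for `date`.")
  parsed_date <- as.Date(raw$date, format = date_format)

  num <- function(v) suppressWarnings(as.numeric(v))
  out <- tibble(
    statefips = num(raw$statefips), countyfips = num(raw$countyfips),
    year = num(raw$year), date = parsed_date,
    pm25_max_pred = num(raw$pm25_max_pred),
    pm25_med_pred = num(raw$pm25_med_pred),
    pm25_mean_pred = num(raw$pm25_mean_pred),
    pm25_pop_pred = num(raw$pm25_pop_pred)
  )

  reason <- rep(NA_character_, nrow(out))
  conc <- as.matrix(out[pm25_columns])
  bad_date <- is.na(out$date)
  bad_fips <- is.na(out$statefips) | is.na(out$countyfips) | is.na(out$year)
  bad_conc <- apply(conc, 1, function(r) any(is.na(r) | r < 0))
  year_mismatch <- !bad_date & !is.na(out$year) &
    as.integer(format(out$date, "%Y")) != out$year
  reason[year_mismatch] <- "date year does not match the year column"
  reason[bad_conc] <- "non-numeric or negative concentration"
  reason[bad_fips] <- "non-numeric FIPS or year"
  reason[bad_date] <- "unparseable date"

  keep <- is.na(reason)
  rejects <- tibble(row = which(!keep), reason = reason[!keep])
  clean <- out[keep, , drop = FALSE]
  clean$statefips <- as.integer(clean$statefips)
  clean$countyfips <- as.integer(clean$countyfips)
  clean$year <- as.integer(clean$year)
  attr(clean, "rejects") <- rejects
  attr(clean, "date_format") <- date_format
  clean
}

#' Extract one county's daily series
#'
#' Filters the records of [read_cdc_pm25()] to a county and one of the
#' four concentration columns, sorted chronologically. Duplicate dates
#' are an error (listed in the message); an unknown county is an error.
#'
#' @param records Tibble of records.
#' @param countyfips County FIPS code.
#' @param variable One of `"pm25_max_pred"`, `"pm25_med_pred"`,
#'   `"pm25_mean_pred"`, `"pm25_pop_pred"`.
#' @return A tibble with `date` and `value`, date-ordered.
#' @export
select_series <- function(records, countyfips, variable = "pm25_max_pred") {
  if (!variable %in% pm25_columns) {
    abort(sprintf("`variable` must be one of: %s.",
                  paste(pm25_columns, collapse = ", ")))
  }
  sel <- dplyr::filter(records, .data$countyfips == !!countyfips)
  if (nrow(sel) == 0L) {
    abort(sprintf("no records for county FIPS %s.", countyfips))
  }
  dup <- sel$date[duplicated(sel$date)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate dates for county %s: %s.", countyfips,
                  paste(head(unique(format(dup)), 5), collapse = ", ")))
  }
  sel <- dplyr::arrange(sel, .data$date)
  tibble(date = sel$date, value = sel[[variable]])
}

# spreadsheet-convention (bias-corrected) sample skewness
sample_skewness <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (s == 0 || n < 3) return(NA_real_)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

# spreadsheet-convention excess kurtosis
sample_kurtosis <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (s == 0 || n < 4) return(NA_real_)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Descriptive statistics of a concentration series
#'
#' The summary layout used for daily PM2.5 series: mean, standard error,
#' median, mode (most frequent exact value, smallest on ties), sample
#' standard deviation and variance (n - 1 denominator), bias-corrected
#' excess kurtosis and skewness (spreadsheet conventions), range,
#' extrema, sum and count.
#'
#' @param x Numeric series with at least 2 values.
#' @return A one-row tibble with the thirteen summary columns.
#' @export
descriptive_stats <- function(x) {
  if (length(x) < 2L) abort("need at least 2 observations.")
  if (any(!is.finite(x))) abort("series must be finite.")
  tab <- table(x)
  mode_val <- as.numeric(names(tab)[tab == max(tab)])
  tibble(
    mean = mean(x),
    standard_error = sd(x) / sqrt(length(x)),
    median = median(x),
    mode = min(mode_val),
    standard_deviation = sd(x),
    sample_variance = var(x),
    kurtosis = sample_kurtosis(x),
    skewness = sample_skewness(x),
    range = max(x) - min(x),
    minimum = min(x),
    maximum = max(x),
    sum = sum(x),
    count = length(x)
  )
}

#' Write an analysis report to disk
#'
#' Serializes a tuning report, Friedman result or descriptive-statistics
#' table as JSON (full precision, deterministic field order) or CSV. The
#' CSV layout of a tuning report follows the conventional comparison
#' table column order: Best, Worst, Average, SD, CPU time, C, Alpha.
#'
#' @param report An `svr_tuning_report`, `friedman_rank`, or data frame.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  payload <- report_payload(report)
  if (format == "json") {
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
  } else {
    readr::write_csv(report_csv(report), path)
  }
  invisible(path)
}

report_payload <- function(report) {
  if (inherits(report, "svr_tuning_report")) {
    list(
      type = "svr_tuning_report",
      best = report$best, worst = report$worst, average = report$average,
      sd = report$sd, cpu_time = report$cpu_time,
      C = report$best_C, sigma = report$best_sigma,
      holdout_mape = if (is.null(report$holdout_mape)) NULL else report$holdout_mape,
      master_seed = report$master_seed,
      per_run = report$per_run
    )
  } else if (inherits(report, "friedman_rank")) {
    list(
      type = "friedman_rank",
      mean_ranks = as.list(report$mean_ranks),
      chi_square = report$chi_square, df = report$df,
      p_value = report$p_value, ordinal = as.list(report$ordinal),
      n_blocks = report$n_blocks, k = report$k,
      tie_correction = report$tie_correction
    )
  } else if (is.data.frame(report)) {
    list(type = "table", data = report)
  } else {
    abort("unsupported report type.")
  }
}

report_csv <- function(report) {
  if (inherits(report, "svr_tuning_report")) {
    tibble(Best = report$best, Worst = report$worst,
           Average = report$average, SD = report$sd,
           `CPU Time` = report$cpu_time, C = report$best_C,
           Alpha = report$best_sigma)
  } else if (inherits(report, "friedman_rank")) {
    tidy(report)
  } else if (is.data.frame(report)) {
    report
  } else {
    abort("unsupported report type.")
  }
}
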