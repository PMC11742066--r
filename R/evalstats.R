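# Evaluation metrics for the multi-run protocol and the Friedman rank
# test used to compare optimizers across repeated runs.

#' Mean absolute percentage error
#'
#' `MAPE = mean(|(actual - predicted) / actual|)`. Undefined for a zero
#' actual value, which raises an error rather than returning Inf.
#'
#' @param actual Observed values (all non-zero).
#' @param predicted Predictions of the same length.
#' @return A non-negative scalar (a proportion: 0.1 means 10%).
#' @examples
#' mape(c(100, 200), c(110, 180)) # 0.1
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.")
  }
  if (length(actual) == 0L) abort("empty input.")
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) {
    abort("inputs must be finite.")
  }
  if (any(actual == 0)) {
    abort("`actual` contains zero values; MAPE is undefined.")
  }
  mean(abs((actual - predicted) / actual))
}

#' Summarise repeated-run objective values
#'
#' Best (minimum), worst (maximum), average and standard deviation (with
#' the M - 1 denominator) of the per-run objective values; a single run
#' reports sd = 0 by convention.
#'
#' @param values Numeric vector of per-run objective values (length >= 1).
#' @return A one-row tibble: `best`, `worst`, `average`, `sd`, `n_runs`.
#' @examples
#' summarize_runs(c(3, 1, 2))
#' @export
summarize_runs <- function(values) {
  if (length(values) == 0L) abort("`values` is empty.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  tibble(
    best = min(values), worst = max(values), average = mean(values),
    sd = if (length(values) == 1L) 0 else sd(values),
    n_runs = length(values)
  )
}

# independent of stats::friedman.test: average ranks within blocks,
# chi-square from rank sums, optional classical tie-correction divisor
#' Friedman rank test across repeated runs
#'
#' Compares k algorithms over n blocks (runs): within each block the
#' algorithms are ranked ascending (lower objective = better rank, ties
#' averaged), and the chi-square statistic
#' `12 / (n k (k + 1)) * sum(Rj^2) - 3 n (k + 1)` with column rank sums
#' `Rj` is referred to the upper tail of a chi-square with k - 1 degrees
#' of freedom. With `tie_correction = TRUE` (default) the statistic is
#' divided by `1 - sum(t^3 - t) / (n k (k^2 - 1))`, the classical
#' adjustment for tied ranks; disable it to get the unadjusted statistic.
#'
#' @param x An n x k numeric matrix or data frame, blocks in rows,
#'   algorithms in columns (column names label the algorithms).
#' @param tie_correction Apply the tie-correction divisor. Default `TRUE`.
#' @return A `friedman_rank` object: `mean_ranks`, `rank_sums`,
#'   `chi_square`, `df`, `p_value`, `ordinal` (1 = best mean rank, ties
#'   broken by column order), `n_blocks`, `k`.
#' @examples
#' m <- cbind(a = c(1, 1, 2), b = c(2, 3, 1), c = c(3, 2, 3))
#' friedman_test(m)
#' @export
friedman_test <- function(x, tie_correction = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be numeric.")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) abort("need at least 2 blocks and 2 treatments.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  if (is.null(colnames(x))) colnames(x) <- paste0("algo", seq_len(k))

  ranks <- t(apply(x, 1, rank))
  rank_sums <- colSums(ranks)
  chi <- 12 / (n * k * (k + 1)) * sum(rank_sums^2) - 3 * n * (k + 1)
  if (tie_correction) {
    tie_sum <- sum(apply(x, 1, function(row) {
      tab <- table(row)
      sum(tab^3 - tab)
    }))
    correction <- 1 - tie_sum / (n * k * (k^2 - 1))
    # every block completely tied: no ranking information, statistic is 0
    chi <- if (correction <= 0) 0 else chi / correction
  }
  mean_ranks <- rank_sums / n
  structure(list(
    mean_ranks = mean_ranks,
    rank_sums = rank_sums,
    chi_square = chi,
    df = k - 1L,
    p_value = pchisq(chi, df = k - 1, lower.tail = FALSE),
    ordinal = rank_ordinals(mean_ranks),
    n_blocks = n, k = k,
    tie_correction = tie_correction
  ), class = "friedman_rank")
}

# ordinal ranking by ascending mean rank; equal mean ranks resolved in
# favour of the earlier column (documented tie-break)
rank_ordinals <- function(mean_ranks) {
  ord <- order(mean_ranks, seq_along(mean_ranks))
  out <- integer(length(mean_ranks))
  out[ord] <- seq_along(mean_ranks)
  names(out) <- names(mean_ranks)
  out
}

#' Ordinal algorithm ranking from a Friedman result
#'
#' Position 1 is the algorithm with the smallest mean rank; equal mean
#' ranks are broken by column order.
#'
#' @param x A `friedman_rank` object or a named numeric vector of mean
#'   ranks.
#' @return A named integer vector of ordinals (a permutation of 1..k).
#' @export
rank_algorithms <- function(x) {
  if (inherits(x, "friedman_rank")) return(x$ordinal)
  if (!is.numeric(x)) abort("`x` must be a friedman_rank or numeric vector.")
  rank_ordinals(x)
}

#' @export
print.friedman_rank <- function(x, ...) {
  cat(sprintf("<Friedman rank test: %d blocks x %d algorithms>\n",
              x$n_blocks, x$k))
  cat(sprintf("  chi-square = %.4f (df = %d), p = %.4g%s\n",
              x$chi_square, x$df, x$p_value,
              if (x$tie_correction) ", tie-corrected" else ""))
  print(round(x$mean_ranks, 3))
  invisible(x)
}

#' @rdname friedman_test
#' @param x A `friedman_rank` (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy friedman_rank
#' @export
tidy.friedman_rank <- function(x, ...) {
  tibble(
    algorithm = names(x$mean_ranks),
    mean_rank = as.numeric(x$mean_ranks),
    rank_sum = as.numeric(x$rank_sums),
    ordinal = as.integer(x$ordinal)
  )
}

#' @rdname friedman_test
#' @method glance friedman_rank
#' @export
glance.friedman_rank <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value,
         n_blocks = x$n_blocks, k = x$k, tie_correction = x$tie_correction)
}

#' @rdname friedman_test
#' @param object A `friedman_rank`.
#' @method autoplot friedman_rank
#' @export
autoplot.friedman_rank <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$algorithm, .data$mean_rank),
    y = .data$mean_rank)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean rank (lower is better)",
                  title = sprintf("Friedman test: chi-sq = %.2f, p = %.3g",
                                  object$chi_square, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Packaged per-run MAPE comparison matrices
#'
#' Ten-run by eight-algorithm MAPE matrices for the five county-level
#' PM2.5 datasets (FIPS 1001, 1003, 1005, 1007, 1009), as published for
#' the eight metaheuristic-tuned SVR hybrids. Used as fixtures for the
#' Friedman ranking.
#'
#' @param county One of 1001, 1003, 1005, 1007, 1009.
#' @return A tibble with a `run` column and one column per algorithm.
#' @export
mape_run_table <- function(county) {
  county <- as.integer(county)
  path <- system.file("extdata", sprintf("mape_runs_%d.csv", county),
                      package = "hawksvr")
  if (path == "") abort(sprintf("no packaged MAPE table for county %s.", county))
  readr::read_csv(path, show_col_types = FALSE)
}
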