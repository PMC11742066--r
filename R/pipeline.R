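# The forecasting workflow: min-max scaling, autoregressive lag
# embedding, the k-fold cross-validated MAPE tuning objective, the
# HHO-driven tuning trial, and the repeated-run experiment harness.

#' Min-max normalization of a series
#'
#' Affine rescaling onto \[0, 1\]: `(x - min) / (max - min)`. The fitted
#' extrema are returned so forecasts can be mapped back to concentration
#' units with [minmax_inverse()].
#'
#' @param x Numeric series (length >= 2, non-constant).
#' @return A list with `values` (normalized series) and `params`
#'   (a `minmax_params` object with `min_val`, `max_val`).
#' @examples
#' minmax_normalize(c(2, 4, 6))$values # 0, 0.5, 1
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2L) abort("series must have length >= 2.")
  if (any(!is.finite(x))) abort("series must be finite.")
  rng <- range(x)
  if (rng[1] == rng[2]) abort("constant series: zero range, cannot normalize.")
  params <- structure(list(min_val = rng[1], max_val = rng[2]),
                      class = "minmax_params")
  list(values = (x - rng[1]) / (rng[2] - rng[1]), params = params)
}

#' Invert a min-max normalization
#'
#' @param x Normalized values.
#' @param params A `minmax_params` object from [minmax_normalize()].
#' @return Values on the original concentration scale.
#' @export
minmax_inverse <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  x * (params$max_val - params$min_val) + params$min_val
}

#' Autoregressive lag embedding of a series
#'
#' Sliding-window supervised set: row t holds the `n_lags` consecutive
#' values starting at t, and the target is the value `horizon` steps
#' after the window. Yields `length(x) - n_lags - horizon + 1` rows.
#'
#' @param x Numeric series (typically already normalized).
#' @param n_lags Number of autoregressive lags (>= 1). Default 7.
#' @param horizon Steps ahead to forecast (>= 1). Default 1.
#' @param index Optional chronological index (e.g. dates) aligned with
#'   `x`; the returned `index` column marks each target's position.
#' @return A tibble with columns `lag_1` ... `lag_<n_lags>`, `target`,
#'   and optionally `index`.
#' @examples
#' lag_embed(1:4, n_lags = 2) # features (1,2),(2,3); targets 3, 4
#' @export
lag_embed <- function(x, n_lags = 7, horizon = 1, index = NULL) {
  n_lags <- check_count(n_lags, "n_lags", 1L)
  horizon <- check_count(horizon, "horizon", 1L)
  n <- length(x)
  n_rows <- n - n_lags - horizon + 1L
  if (n_rows < 1L) {
    abort(sprintf("series of length %d is too short for %d lags at horizon %d.",
                  n, n_lags, horizon))
  }
  feats <- vapply(seq_len(n_lags),
                  function(j) x[seq.int(j, length.out = n_rows)],
                  numeric(n_rows))
  feats <- matrix(feats, nrow = n_rows,
                  dimnames = list(NULL, paste0("lag_", seq_len(n_lags))))
  out <- as_tibble(feats)
  out$target <- x[seq.int(n_lags + horizon, length.out = n_rows)]
  if (!is.null(index)) {
    if (length(index) != n) abort("`index` must align with `x`.")
    out$index <- index[seq.int(n_lags + horizon, length.out = n_rows)]
  }
  out
}

#' Cross-validation fold plan
#'
#' Partitions `1:n` into `k` disjoint folds whose sizes differ by at most
#' one. `method = "random"` shuffles before splitting (the default);
#' `method = "blocked"` keeps contiguous runs for time-ordered data.
#'
#' @param n Number of samples.
#' @param k Number of folds (2 <= k <= n).
#' @param method `"random"` or `"blocked"`.
#' @return A list of `k` integer index vectors.
#' @export
kfold_plan <- function(n, k, method = c("random", "blocked")) {
  n <- check_count(n, "n", 2L)
  k <- check_count(k, "k", 2L)
  if (n < k) abort(sprintf("cannot split %d samples into %d folds.", n, k))
  method <- match.arg(method)
  idx <- if (method == "random") sample.int(n) else seq_len(n)
  unname(split(idx, rep(seq_len(k), length.out = n)))
}

# extract the feature matrix and target vector from a supervised tibble
supervised_matrices <- function(data) {
  data <- as_tibble(data)
  if (!"target" %in% names(data)) abort("`data` must have a `target` column.")
  feat_cols <- setdiff(names(data), c("target", "index"))
  if (length(feat_cols) == 0L) abort("`data` has no feature columns.")
  x <- as.matrix(data[feat_cols])
  storage.mode(x) <- "double"
  list(x = x, y = as.numeric(data$target))
}

#' k-fold cross-validated MAPE objective for SVR hyperparameters
#'
#' Builds the scalar objective minimised during tuning. For a decision
#' vector `(C, sigma)` it fits the SVR on k - 1 folds, predicts the held
#' fold, maps predictions and targets back to the original concentration
#' scale when normalization parameters are supplied, and averages the k
#' fold MAPEs. The fold plan is fixed when the closure is created, so the
#' objective is deterministic.
#'
#' @param data Supervised tibble with feature columns and a `target`
#'   column (see [lag_embed()]).
#' @param k_folds Number of folds. Default 10.
#' @param norm_params Optional `minmax_params`; when given, MAPE is
#'   computed on the inverse-normalized scale.
#' @param epsilon SVR tube half-width. Default 0.1.
#' @param tol Dual-solver stopping tolerance used inside tuning. The
#'   search only needs MAPE at search resolution, so the default (1e-4)
#'   is looser than the final-fit contract.
#' @param solver_budget Iteration budget per fold fit, expressed per
#'   training sample (default 50). At the budget the feasible iterate is
#'   accepted, as SVM libraries do during model selection, which bounds
#'   the cost of ill-conditioned corners of the hyperparameter box; final
#'   model fits via [svr_fit()] keep the strict convergence contract.
#' @param folds Optional explicit fold plan (overrides `k_folds`).
#' @param method Fold construction passed to [kfold_plan()].
#' @return A function `position -> cv_mape` with attributes `folds` and
#'   `n`.
#' @export
cv_mape_objective <- function(data, k_folds = 10, norm_params = NULL,
                              epsilon = 0.1, tol = 1e-4, solver_budget = 50,
                              folds = NULL, method = "random") {
  mats <- supervised_matrices(data)
  n <- length(mats$y)
  if (is.null(folds)) folds <- kfold_plan(n, k_folds, method = method)
  d2 <- sqdist(mats$x)  # shared across evaluations
  y <- mats$y

  objective <- function(position) {
    if (length(position) != 2L) abort("`position` must be (C, sigma).")
    C <- position[1]
    sigma <- position[2]
    check_number(C, "C", 0, strict = TRUE)
    check_number(sigma, "sigma", 0, strict = TRUE)
    kmat <- exp(-d2 / (2 * sigma^2))
    fold_mape <- vapply(seq_along(folds), function(fi) {
      test <- folds[[fi]]
      train <- setdiff(seq_len(n), test)
      sol <- tryCatch(
        svr_fit_kernel(kmat[train, train, drop = FALSE], y[train],
                       C, sigma, epsilon, tol,
                       max_iter = solver_budget * length(train),
                       allow_partial = TRUE),
        error = function(e) abort(sprintf("fold %d: %s", fi, conditionMessage(e)))
      )
      pred <- drop(kmat[test, train, drop = FALSE] %*% sol$beta) + sol$bias
      actual <- y[test]
      if (!is.null(norm_params)) {
        pred <- minmax_inverse(pred, norm_params)
        actual <- minmax_inverse(actual, norm_params)
      }
      mape(actual, pred)
    }, numeric(1))
    mean(fold_mape)
  }
  attr(objective, "folds") <- folds
  attr(objective, "n") <- n
  objective
}

#' Tuning configuration
#'
#' Settings for a hyperparameter-tuning experiment: the optimizer
#' plug-in, its evaluation budget, the repeated-run count, the (C, sigma)
#' search bounds, and the cross-validation layout.
#'
#' @param optimizer Registered optimizer name or function; see
#'   [get_optimizer()]. Default `"hho"`.
#' @param n_agents Population size. Default 30.
#' @param max_iter Iterations per run. Default 50.
#' @param runs Independent repetitions. Default 10.
#' @param bounds Length-2 lower/upper bound applied to both C and sigma.
#'   Default `c(1, 1000)`.
#' @param k_folds Cross-validation folds. Default 10.
#' @param epsilon SVR tube half-width. Default 0.1.
#' @param tol Dual-solver tolerance used inside tuning. Default 1e-4; see
#'   [cv_mape_objective()].
#' @param solver_budget Per-sample iteration budget of tuning fits.
#' @return A `tuning_config` object.
#' @export
tuning_config <- function(optimizer = "hho", n_agents = 30, max_iter = 50,
                          runs = 10, bounds = c(1, 1000), k_folds = 10,
                          epsilon = 0.1, tol = 1e-4, solver_budget = 50) {
  runs <- check_count(runs, "runs", 1L)
  k_folds <- check_count(k_folds, "k_folds", 2L)
  if (length(bounds) != 2L || !is.numeric(bounds) || bounds[1] >= bounds[2]) {
    abort("`bounds` must be an increasing length-2 numeric vector.")
  }
  structure(list(
    optimizer = optimizer, n_agents = check_count(n_agents, "n_agents", 2L),
    max_iter = check_count(max_iter, "max_iter", 1L), runs = runs,
    bounds = as.numeric(bounds), k_folds = k_folds,
    epsilon = check_number(epsilon, "epsilon", 0),
    tol = check_number(tol, "tol", 0, strict = TRUE),
    solver_budget = check_count(solver_budget, "solver_budget", 1L)
  ), class = "tuning_config")
}

#' Run one hyperparameter-tuning trial
#'
#' Draws a fold plan, builds the cross-validated MAPE objective, and
#' lets the configured optimizer search the (C, sigma) box. Fully
#' deterministic under a fixed seed.
#'
#' @param data Supervised tibble (feature columns plus `target`).
#' @param config A [tuning_config()].
#' @param norm_params Optional `minmax_params` for original-scale MAPE.
#' @param seed Optional integer seed.
#' @return An `svr_trial`: `best_C`, `best_sigma`, `best_mape`,
#'   `convergence`, `n_evals`, `elapsed`, `folds`, and the raw optimizer
#'   `result`.
#' @export
tune_svr <- function(data, config = tuning_config(), norm_params = NULL,
                     seed = NULL) {
  stopifnot(inherits(config, "tuning_config"))
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  objective <- cv_mape_objective(
    data, k_folds = config$k_folds, norm_params = norm_params,
    epsilon = config$epsilon, tol = config$tol,
    solver_budget = config$solver_budget)
  space <- search_space(config$bounds[1], config$bounds[2], dim = 2)
  optimizer <- get_optimizer(config$optimizer)
  result <- optimizer(objective, space,
                      hho_options(config$n_agents, config$max_iter),
                      seed = NULL)
  structure(list(
    best_C = result$best_position[1],
    best_sigma = result$best_position[2],
    best_mape = result$best_fitness,
    convergence = result$convergence,
    n_evals = result$n_evals,
    elapsed = proc.time()[["elapsed"]] - t0,
    folds = attr(objective, "folds"),
    objective = objective,
    result = result,
    seed = seed
  ), class = "svr_trial")
}

# per-run seeds derived deterministically from the master seed
derive_run_seeds <- function(master_seed, runs) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, runs)
}

#' Repeated-run tuning experiment
#'
#' Executes `config$runs` independent tuning trials with per-run seeds
#' derived deterministically from `master_seed`, and aggregates the
#' per-run best MAPEs into the best/worst/average/sd summary.
#'
#' @inheritParams tune_svr
#' @param master_seed Integer master seed for the experiment.
#' @return An `svr_tuning_report`: summary fields (`best`, `worst`,
#'   `average`, `sd`), `cpu_time`, the best run's `best_C`/`best_sigma`,
#'   a `per_run` tibble, and the per-run convergence curves.
#' @export
run_experiment <- function(data, config = tuning_config(), norm_params = NULL,
                           master_seed = 1) {
  stopifnot(inherits(config, "tuning_config"))
  seeds <- derive_run_seeds(master_seed, config$runs)
  t0 <- proc.time()[["elapsed"]]
  trials <- purrr::imap(seeds, function(s, run) {
    trial <- tryCatch(
      tune_svr(data, config, norm_params, seed = s),
      error = function(e) abort(sprintf("run %d (seed %d) failed: %s",
                                        run, s, conditionMessage(e))))
    trial
  })
  per_run <- purrr::imap_dfr(trials, function(tr, run) {
    tibble(run = run, seed = seeds[run], mape = tr$best_mape,
           C = tr$best_C, sigma = tr$best_sigma, elapsed = tr$elapsed)
  })
  summ <- summarize_runs(per_run$mape)
  best_run <- which.min(per_run$mape)
  structure(list(
    best = summ$best, worst = summ$worst, average = summ$average,
    sd = summ$sd,
    cpu_time = proc.time()[["elapsed"]] - t0,
    best_C = per_run$C[best_run], best_sigma = per_run$sigma[best_run],
    per_run = per_run,
    convergence = purrr::map(trials, "convergence"),
    config = config, master_seed = master_seed
  ), class = "svr_tuning_report")
}

#' Compare optimizers under identical conditions
#'
#' Runs the same repeated-run experiment for each optimizer plug-in with
#' identical data, budget and per-run seeds, then ranks the optimizers'
#' per-run best MAPEs with the Friedman test.
#'
#' @inheritParams run_experiment
#' @param optimizers Character vector of registered optimizer names (or
#'   list of functions obeying the optimizer contract); at least 2.
#' @return An `optimizer_comparison`: `mape_matrix` (tibble, one column
#'   per optimizer plus `run`), `rank_result` (a `friedman_rank`), and
#'   the per-optimizer reports.
#' @export
run_comparison <- function(data, config = tuning_config(), norm_params = NULL,
                           optimizers = c("hho", "random"), master_seed = 1) {
  if (length(optimizers) < 2L) abort("need at least 2 optimizers to compare.")
  labels <- if (is.null(names(optimizers))) {
    if (is.character(optimizers)) optimizers else paste0("opt", seq_along(optimizers))
  } else names(optimizers)
  labels <- make.unique(labels)
  reports <- purrr::map(seq_along(optimizers), function(i) {
    cfg <- config
    cfg$optimizer <- optimizers[[i]]
    run_experiment(data, cfg, norm_params, master_seed = master_seed)
  })
  names(reports) <- labels
  mat <- matrix(unlist(purrr::map(reports, ~ .x$per_run$mape)),
                ncol = length(reports),
                dimnames = list(NULL, labels))
  rank_result <- friedman_test(mat)
  structure(list(
    mape_matrix = dplyr::bind_cols(tibble(run = seq_len(config$runs)),
                                   as_tibble(mat)),
    rank_result = rank_result,
    reports = reports
  ), class = "optimizer_comparison")
}

#' Prepare a daily series for forecasting
#'
#' Applies the pre-processing phase: optional chronological holdout
#' split, min-max normalization (fitted on the training portion by
#' default to avoid leakage, or on the whole series), and lag embedding.
#'
#' @param series Numeric vector of daily concentrations, or a tibble with
#'   `date` and `value` columns as returned by [select_series()].
#' @param n_lags,horizon Lag-embedding layout; see [lag_embed()].
#' @param holdout_frac Fraction of the most recent observations reserved
#'   for final evaluation (0 for none).
#' @param normalize `"train"` (fit extrema on the training portion; the
#'   leakage-safe default) or `"full"` (whole series).
#' @return A list with `train` and `test` supervised tibbles (the test
#'   embedding reuses the last training values as context), and
#'   `norm_params`.
#' @export
pm25_forecast_data <- function(series, n_lags = 7, horizon = 1,
                               holdout_frac = 0,
                               normalize = c("train", "full")) {
  normalize <- match.arg(normalize)
  index <- NULL
  if (is.data.frame(series)) {
    if (!all(c("date", "value") %in% names(series))) {
      abort("a data-frame `series` needs `date` and `value` columns.")
    }
    index <- series$date
    series <- series$value
  }
  check_number(holdout_frac, "holdout_frac", 0)
  if (holdout_frac >= 1) abort("`holdout_frac` must be < 1.")
  n <- length(series)
  n_test <- floor(n * holdout_frac)
  n_train <- n - n_test
  fit_on <- if (normalize == "train") series[seq_len(n_train)] else series
  norm <- minmax_normalize(fit_on)
  scaled <- (series - norm$params$min_val) /
    (norm$params$max_val - norm$params$min_val)
  embedded <- lag_embed(scaled, n_lags, horizon, index = index)
  # rows whose target falls in the holdout window form the test set
  target_pos <- seq.int(n_lags + horizon, length.out = nrow(embedded))
  is_test <- target_pos > n_train
  list(
    train = embedded[!is_test, , drop = FALSE],
    test = if (n_test > 0) embedded[is_test, , drop = FALSE] else NULL,
    norm_params = norm$params,
    n_lags = n_lags, horizon = horizon, normalize = normalize
  )
}

#' Tune and evaluate a PM2.5 forecaster end to end
#'
#' The complete workflow for one daily series: pre-processing
#' ([pm25_forecast_data()]), repeated-run HHO tuning of (C, sigma)
#' against the cross-validated MAPE ([run_experiment()]), a final fit at
#' the best hyperparameters, and holdout evaluation on the original
#' concentration scale.
#'
#' @inheritParams pm25_forecast_data
#' @param config A [tuning_config()].
#' @param master_seed Integer master seed.
#' @return An `svr_tuning_report` with additional `holdout_mape` and
#'   `final_model` entries when a holdout was reserved.
#' @export
pm25_tune <- function(series, config = tuning_config(), n_lags = 7,
                      horizon = 1, holdout_frac = 0.2,
                      normalize = c("train", "full"), master_seed = 1) {
  prep <- pm25_forecast_data(series, n_lags, horizon, holdout_frac, normalize)
  report <- run_experiment(prep$train, config, prep$norm_params, master_seed)
  report$n_lags <- n_lags
  report$horizon <- horizon
  report$norm_params <- prep$norm_params
  if (!is.null(prep$test) && nrow(prep$test) > 0) {
    mats <- supervised_matrices(prep$train)
    model <- svr_fit(mats$x, mats$y, C = report$best_C,
                     sigma = report$best_sigma, epsilon = config$epsilon)
    tmats <- supervised_matrices(prep$test)
    pred <- predict(model, tmats$x)
    report$holdout_mape <- mape(minmax_inverse(tmats$y, prep$norm_params),
                                minmax_inverse(pred, prep$norm_params))
    report$final_model <- model
  }
  report
}

#' @export
print.svr_tuning_report <- function(x, ...) {
  cat("<SVR tuning report>\n")
  cat(sprintf("  runs: %d | best %.6g | worst %.6g | average %.6g | sd %.3g\n",
              nrow(x$per_run), x$best, x$worst, x$average, x$sd))
  cat(sprintf("  best (C, sigma) = (%.4g, %.4g) | cpu %.1fs\n",
              x$best_C, x$best_sigma, x$cpu_time))
  if (!is.null(x$holdout_mape)) {
    cat(sprintf("  holdout MAPE: %.6g\n", x$holdout_mape))
  }
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `svr_tuning_report` (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy svr_tuning_report
#' @export
tidy.svr_tuning_report <- function(x, ...) x$per_run

#' @rdname run_experiment
#' @method glance svr_tuning_report
#' @export
glance.svr_tuning_report <- function(x, ...) {
  tibble(best = x$best, worst = x$worst, average = x$average, sd = x$sd,
         cpu_time = x$cpu_time, C = x$best_C, sigma = x$best_sigma,
         runs = nrow(x$per_run))
}

#' @rdname run_experiment
#' @param object An `svr_tuning_report`.
#' @method autoplot svr_tuning_report
#' @export
autoplot.svr_tuning_report <- function(object, ...) {
  curves <- purrr::imap_dfr(object$convergence, function(cv, run) {
    dplyr::mutate(cv, run = factor(run))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$iteration,
                                       y = .data$best_fitness,
                                       colour = .data$run)) +
    ggplot2::geom_step(alpha = 0.8) +
    ggplot2::labs(x = "Iteration", y = "Best CV-MAPE so far", colour = "Run") +
    ggplot2::theme_minimal()
}
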