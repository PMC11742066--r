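# epsilon-insensitive support vector regression with Gaussian RBF kernel.
# The dual box QP is solved by the compiled SMO routine in src/smo.cpp;
# the model keeps the signed dual coefficients beta_i = alpha*_i - alpha_i,
# the bias, and the training inputs needed for the kernel expansion.

#' Gaussian RBF kernel
#'
#' `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`, symmetric, in (0, 1].
#'
#' @param x,x2 Numeric vectors of equal length.
#' @param sigma Kernel width (> 0).
#' @return The scalar kernel value.
#' @export
rbf_kernel <- function(x, x2, sigma) {
  check_number(sigma, "sigma", 0, strict = TRUE)
  if (length(x) != length(x2)) abort("`x` and `x2` must have equal length.")
  exp(-sum((x - x2)^2) / (2 * sigma^2))
}

# squared euclidean cross-distances, n x m
sqdist <- function(x, x2 = NULL) {
  x <- as.matrix(x)
  x2 <- if (is.null(x2)) x else as.matrix(x2)
  d2 <- outer(rowSums(x^2), rep(1, nrow(x2))) +
    outer(rep(1, nrow(x)), rowSums(x2^2)) - 2 * tcrossprod(x, x2)
  pmax(d2, 0)
}

#' RBF Gram matrix
#'
#' Kernel matrix between the rows of `x` and `x2` (or `x` with itself):
#' symmetric with unit diagonal in the square case, entries in (0, 1].
#'
#' @param x,x2 Numeric matrices with matching column count; `x2 = NULL`
#'   gives the square Gram matrix of `x`.
#' @inheritParams rbf_kernel
#' @return An `nrow(x)` x `nrow(x2)` matrix.
#' @export
rbf_gram <- function(x, x2 = NULL, sigma) {
  check_number(sigma, "sigma", 0, strict = TRUE)
  exp(-sqdist(x, x2) / (2 * sigma^2))
}

# fit from a precomputed training Gram matrix (shared by svr_fit and the
# cross-validation objective, which reuses one distance matrix per dataset).
# `allow_partial` accepts the feasible iterate at the iteration cap instead
# of erroring — used during hyperparameter search, where the objective only
# needs search-resolution accuracy and a bounded per-fit effort
svr_fit_kernel <- function(kmat, y, C, sigma, epsilon, tol, max_iter = NULL,
                           allow_partial = FALSE) {
  n <- length(y)
  if (is.null(max_iter)) max_iter <- 1e4 * n
  sol <- smo_solve(kmat, y, C, epsilon, tol, as.integer(max_iter))
  if (!sol$converged && !allow_partial) {
    abort(sprintf(
      "SVR dual solver did not converge within %d iterations (KKT residual %.3g > %.3g).",
      as.integer(max_iter), sol$gap, tol))
  }
  sol
}

#' Fit an epsilon-insensitive RBF support vector regression
#'
#' Solves the kernelised dual problem subject to the balance constraint
#' `sum(alpha* - alpha) = 0` and box constraints `0 <= alpha, alpha* <= C`
#' with a sequential-minimal-optimization solver, then recovers the bias
#' as the average over unbounded support vectors (midpoint of the
#' KKT-feasible interval when none exist).
#'
#' @param x Numeric matrix or data frame of predictors (n x d, n >= 2).
#' @param y Numeric targets of length n.
#' @param C Box/penalty constant (> 0): trade-off between flatness and
#'   tolerated training error.
#' @param sigma RBF kernel width (> 0).
#' @param epsilon Insensitivity tube half-width (>= 0). Residuals inside
#'   the tube carry no loss. Default 0.1, intended for targets on a
#'   normalized \[0, 1\] scale.
#' @param tol KKT-violation stopping tolerance of the dual solver.
#' @param max_iter Iteration cap; defaults to `1e4 * n`. Non-convergence
#'   raises an error carrying the residual.
#' @return An `svr_model`: dual `coeffs` (`alpha* - alpha`), `bias`,
#'   retained `train_inputs`/`train_targets`, `params`, and `diagnostics`
#'   (dual objective, KKT residual, support-vector count, iterations).
#' @examples
#' x <- matrix(0:3)
#' fit <- svr_fit(x, c(0, 1, 2, 3), C = 10, sigma = 1, epsilon = 0.1)
#' predict(fit, x)
#' @export
svr_fit <- function(x, y, C, sigma, epsilon = 0.1, tol = 1e-8,
                    max_iter = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("`x` and `y` sizes disagree.")
  if (length(y) < 2L) abort("at least 2 training samples are required.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite.")
  check_number(C, "C", 0, strict = TRUE)
  check_number(sigma, "sigma", 0, strict = TRUE)
  check_number(epsilon, "epsilon", 0)

  kmat <- rbf_gram(x, sigma = sigma)
  sol <- svr_fit_kernel(kmat, y, C, sigma, epsilon, tol, max_iter)
  structure(list(
    coeffs = as.numeric(sol$beta),
    bias = sol$bias,
    train_inputs = x,
    train_targets = y,
    params = list(C = C, sigma = sigma, epsilon = epsilon),
    diagnostics = list(
      dual_objective = sol$dual_objective,
      kkt_residual = sol$gap,
      n_support = sum(abs(sol$beta) > 1e-10 * C),
      n_unbounded = sol$n_unbounded,
      iterations = sol$iterations,
      tol = tol
    )
  ), class = "svr_model")
}

#' Predict from a fitted SVR model
#'
#' Support-vector expansion `f(x) = sum_i coeffs_i K(x_i, x) + bias`.
#'
#' @param object An `svr_model`.
#' @param newdata Matrix or data frame with the training dimensionality.
#' @param ... Unused.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$train_inputs)) {
    abort(sprintf("`newdata` has %d columns; the model was trained on %d.",
                  ncol(newdata), ncol(object$train_inputs)))
  }
  kcross <- rbf_gram(newdata, object$train_inputs, object$params$sigma)
  drop(kcross %*% object$coeffs) + object$bias
}

#' KKT residual of a fitted SVR model
#'
#' Maximum violation of the first-order optimality conditions of the dual
#' at the model's coefficients (the maximal-violating-pair gap). Zero
#' means exact optimality; the fitted model reports a residual no larger
#' than its stopping tolerance.
#'
#' @param model An `svr_model`.
#' @param x,y Training data; defaults to the data stored in the model.
#' @param coeffs Optionally override the dual coefficients (e.g. to probe
#'   a perturbed solution).
#' @return A non-negative scalar.
#' @export
svr_kkt_residual <- function(model, x = model$train_inputs,
                             y = model$train_targets,
                             coeffs = model$coeffs) {
  kmat <- rbf_gram(as.matrix(x), sigma = model$params$sigma)
  smo_kkt_gap(kmat, as.numeric(y), as.numeric(coeffs),
              model$params$C, model$params$epsilon)
}

#' Dual objective value of a coefficient vector
#'
#' The minimisation form of the SVR dual:
#' `1/2 beta' K beta + epsilon * sum|beta| - y' beta`.
#'
#' @inheritParams svr_kkt_residual
#' @return The scalar dual objective.
#' @export
svr_dual_objective <- function(model, coeffs = model$coeffs) {
  kmat <- rbf_gram(model$train_inputs, sigma = model$params$sigma)
  beta <- as.numeric(coeffs)
  0.5 * drop(beta %*% kmat %*% beta) +
    model$params$epsilon * sum(abs(beta)) -
    sum(model$train_targets * beta)
}

#' @export
print.svr_model <- function(x, ...) {
  d <- x$diagnostics
  cat("<epsilon-SVR model (RBF kernel)>\n")
  cat(sprintf("  n = %d, d = %d | C = %.4g, sigma = %.4g, epsilon = %.3g\n",
              nrow(x$train_inputs), ncol(x$train_inputs),
              x$params$C, x$params$sigma, x$params$epsilon))
  cat(sprintf("  support vectors: %d (%d unbounded) | KKT residual %.2e\n",
              d$n_support, d$n_unbounded, d$kkt_residual))
  invisible(x)
}

#' @rdname svr_fit
#' @param x An `svr_model` (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy svr_model
#' @export
tidy.svr_model <- function(x, ...) {
  C <- x$params$C
  tibble(
    sample = seq_along(x$coeffs),
    coefficient = x$coeffs,
    support = abs(x$coeffs) > 1e-10 * C,
    bounded = abs(x$coeffs) >= C * (1 - 1e-10)
  )
}

#' @rdname svr_fit
#' @method glance svr_model
#' @export
glance.svr_model <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    n = nrow(x$train_inputs), C = x$params$C, sigma = x$params$sigma,
    epsilon = x$params$epsilon, n_support = d$n_support,
    n_unbounded = d$n_unbounded, dual_objective = d$dual_objective,
    kkt_residual = d$kkt_residual, iterations = d$iterations
  )
}

#' Serialize an SVR model to JSON
#'
#' Flat full-precision record of coefficients, bias, hyperparameters and
#' training inputs; [svr_deserialize()] restores a model whose
#' predictions are bit-identical.
#'
#' @param model An `svr_model`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
svr_serialize <- function(model, path) {
  rec <- list(
    coeffs = model$coeffs, bias = model$bias,
    C = model$params$C, sigma = model$params$sigma,
    epsilon = model$params$epsilon,
    train_inputs = model$train_inputs,
    train_targets = model$train_targets,
    diagnostics = model$diagnostics
  )
  jsonlite::write_json(rec, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname svr_serialize
#' @export
svr_deserialize <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coeffs = as.numeric(rec$coeffs), bias = rec$bias,
    train_inputs = as.matrix(rec$train_inputs),
    train_targets = as.numeric(rec$train_targets),
    params = list(C = rec$C, sigma = rec$sigma, epsilon = rec$epsilon),
    diagnostics = rec$diagnostics
  ), class = "svr_model")
}
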