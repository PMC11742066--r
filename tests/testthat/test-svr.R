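# SVR dual solver correctness: kernel algebra, constraint satisfaction,
# agreement with an independent convex-program oracle, KKT diagnostics.

test_that("rbf kernel values and symmetry", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), sigma = 0.7), 1)
  # squared distance equal to 2 sigma^2 gives exp(-1)
  expect_equal(rbf_kernel(0, sqrt(2) * 0.5, sigma = 0.5), exp(-1))
  set.seed(1)
  for (i in 1:5) {
    x <- runif(3)
    y <- runif(3)
    expect_equal(rbf_kernel(x, y, 1.3), rbf_kernel(y, x, 1.3))
  }
  expect_error(rbf_kernel(1, 1, sigma = 0), "sigma")
  expect_error(rbf_kernel(c(1, 2), 1, sigma = 1), "equal length")
})

test_that("gram matrix matches the pairwise kernel and is PSD", {
  set.seed(2)
  x <- matrix(runif(30), 10, 3)
  g <- rbf_gram(x, sigma = 0.8)
  expect_equal(diag(g), rep(1, 10))
  loop <- outer(1:10, 1:10, Vectorize(function(i, j) {
    rbf_kernel(x[i, ], x[j, ], 0.8)
  }))
  expect_equal(g, loop, tolerance = 1e-12)
  expect_gte(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("constant targets give the analytic zero-coefficient solution", {
  x <- matrix(0:3)
  fit <- svr_fit(x, rep(5, 4), C = 10, sigma = 1, epsilon = 0.1)
  expect_equal(fit$coeffs, rep(0, 4))
  expect_equal(fit$bias, 5)
  expect_equal(predict(fit, x), rep(5, 4))
  expect_equal(svr_kkt_residual(fit), 0)
  expect_equal(predict(fit, matrix(c(-2, 9))), rep(5, 2))
})

test_that("1-D ramp toy matches the brute-force convex-program oracle", {
  x <- matrix(0:3)
  y <- c(0, 1, 2, 3)
  fit <- svr_fit(x, y, C = 10, sigma = 1, epsilon = 0.1, tol = 1e-10)
  oracle <- svr_dual_oracle(x, y, C = 10, sigma = 1, epsilon = 0.1)
  expect_equal(fit$diagnostics$dual_objective, oracle$dual_objective,
               tolerance = 1e-6)
  expect_lt(abs(sum(fit$coeffs)), 1e-8)
  expect_lte(max(abs(fit$coeffs)), 10 + 1e-10)
})

test_that("random small problems agree with the oracle in objective and predictions", {
  for (seed in 1:5) {
    toy <- random_svr_toy(seed)
    fit <- svr_fit(toy$x, toy$y, toy$C, toy$sigma, toy$epsilon, tol = 1e-10)
    oracle <- svr_dual_oracle(toy$x, toy$y, toy$C, toy$sigma, toy$epsilon)
    expect_equal(fit$diagnostics$dual_objective, oracle$dual_objective,
                 tolerance = 1e-6)
    pred <- predict(fit, toy$x)
    bias_o <- if (is.na(oracle$bias)) fit$bias else oracle$bias
    pred_o <- unname(drop(oracle$kmat %*% oracle$beta) + bias_o)
    expect_equal(pred, pred_o, tolerance = 1e-4)
    expect_lte(svr_kkt_residual(fit), 1e-6)
    expect_lt(abs(sum(fit$coeffs)), 1e-8)
    expect_lte(max(abs(fit$coeffs)), toy$C * (1 + 1e-12))
  }
})

test_that("interior support vectors sit on the tube boundary", {
  for (seed in 1:3) {
    toy <- random_svr_toy(seed + 10)
    fit <- svr_fit(toy$x, toy$y, toy$C, toy$sigma, toy$epsilon, tol = 1e-10)
    resid <- abs(predict(fit, toy$x) - toy$y)
    interior <- abs(fit$coeffs) > 1e-8 * toy$C &
      abs(fit$coeffs) < toy$C * (1 - 1e-8)
    expect_true(all(resid[interior] <= toy$epsilon + 1e-4))
  }
})

test_that("perturbing an optimal coefficient strictly increases the KKT residual", {
  toy <- random_svr_toy(3)
  fit <- svr_fit(toy$x, toy$y, toy$C, toy$sigma, toy$epsilon, tol = 1e-10)
  base <- svr_kkt_residual(fit)
  pert <- fit$coeffs
  pert[1] <- pert[1] + 0.1 * toy$C
  expect_gt(svr_kkt_residual(fit, coeffs = pert), base + 1e-3)
})

test_that("training error decreases with C on smooth noiseless data", {
  set.seed(4)
  x <- matrix(seq(0, 2 * pi, length.out = 40))
  y <- sin(x[, 1]) + 2.5
  mapes <- vapply(c(0.5, 2, 8, 32, 128), function(C) {
    fit <- svr_fit(x, y, C = C, sigma = 1, epsilon = 0.01)
    mape(y, predict(fit, x))
  }, numeric(1))
  expect_true(all(diff(mapes) <= 1e-10))
})

test_that("serialization round-trips bit-exactly", {
  toy <- random_svr_toy(7)
  fit <- svr_fit(toy$x, toy$y, toy$C, toy$sigma, toy$epsilon)
  path <- tempfile(fileext = ".json")
  svr_serialize(fit, path)
  back <- svr_deserialize(path)
  expect_identical(back$coeffs, fit$coeffs)
  expect_identical(back$bias, fit$bias)
  grid <- matrix(runif(20 * ncol(toy$x), -2, 2), 20)
  expect_identical(predict(back, grid), predict(fit, grid))
})

test_that("degenerate inputs are rejected", {
  expect_error(svr_fit(matrix(1), 1, C = 1, sigma = 1), "at least 2")
  expect_error(svr_fit(matrix(1:4), 1:4, C = -1, sigma = 1), "C")
  expect_error(svr_fit(matrix(1:4), 1:4, C = 1, sigma = 0), "sigma")
  fit <- svr_fit(matrix(1:4), c(1, 2, 3, 4), C = 1, sigma = 1)
  expect_error(predict(fit, matrix(1:4, 2)), "columns")
})

test_that("tidy and glance expose coefficients and diagnostics", {
  toy <- random_svr_toy(5)
  fit <- svr_fit(toy$x, toy$y, toy$C, toy$sigma, toy$epsilon)
  td <- tidy(fit)
  expect_equal(nrow(td), length(toy$y))
  expect_equal(sum(td$support), fit$diagnostics$n_support)
  gl <- glance(fit)
  expect_equal(gl$kkt_residual, fit$diagnostics$kkt_residual)
  expect_lte(gl$kkt_residual, 1e-6)
})
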