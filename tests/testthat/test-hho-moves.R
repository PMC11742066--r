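# Unit behaviour of the individual HHO position-update rules.

test_that("search_space validates and recycles bounds", {
  sp <- search_space(1, 1000, dim = 2)
  expect_equal(sp$lower, c(1, 1))
  expect_equal(sp$upper, c(1000, 1000))
  expect_error(search_space(5, 5), "lower")
  expect_error(search_space(c(0, 2), c(1, 1)), "lower")
  expect_error(search_space(0, 1, dim = 0), "dim")
})

test_that("escape energy follows the linear decay law", {
  expect_equal(hho_escape_energy(0.73, 50, 50), 0)
  expect_equal(hho_escape_energy(-0.2, 50, 50), 0)
  expect_equal(hho_escape_energy(1, 0, 50), 2)
  expect_equal(hho_escape_energy(-0.4, 25, 50), -0.4)
  expect_error(hho_escape_energy(0.5, 1, 0), "max_iter")
  expect_error(hho_escape_energy(0.5, 51, 50), "<=")
})

test_that("escape energy stays inside the decaying envelope", {
  set.seed(11)
  t_max <- 50
  for (t in 0:t_max) {
    e0 <- runif(20, -1, 1)
    e <- vapply(e0, hho_escape_energy, numeric(1), t = t, max_iter = t_max)
    expect_true(all(abs(e) <= 2 * abs(e0) * (1 - t / t_max) + 1e-12))
    expect_true(all(abs(e) <= 2 * (1 - t / t_max) + 1e-12))
  }
})

test_that("levy scale constant matches an independent gamma evaluation", {
  expect_equal(hawksvr:::levy_sigma(1.5), levy_sigma_oracle(1.5),
               tolerance = 1e-12)
  expect_equal(hawksvr:::levy_sigma(1.5), 0.6965745, tolerance = 1e-6)
  for (beta in c(0.5, 1.0, 1.8)) {
    expect_equal(hawksvr:::levy_sigma(beta), levy_sigma_oracle(beta),
                 tolerance = 1e-12)
  }
})

test_that("levy step reproduces its defining formula draw for draw", {
  set.seed(42)
  step <- hho_levy_step(5, beta = 1.5)
  set.seed(42)
  u <- runif(5)
  v <- runif(5)
  expect_equal(step, 0.01 * u * hawksvr:::levy_sigma(1.5) / abs(v)^(1 / 1.5))
  expect_length(hho_levy_step(3), 3)
  expect_true(all(is.finite(hho_levy_step(100))))
})

test_that("exploration move handles both perching branches and clips", {
  sp <- search_space(0, 10, dim = 1)
  # q >= 0.5 with r1 = 0 collapses onto the random hawk
  expect_equal(
    hho_exploration_move(2, 7, 5, 3, sp, q = 0.9, r1 = 0, r2 = 0.4),
    7)
  # q < 0.5 with r3 = 0 gives rabbit - mean (clipped)
  expect_equal(
    hho_exploration_move(2, 7, 5, 3, sp, q = 0.1, r3 = 0, r4 = 0.9),
    2)
  # hand-computed raw value -3 is clipped to the lower bound 0
  expect_equal(
    hho_exploration_move(2, 7, 5, 3, sp, q = 0.1, r3 = 1, r4 = 0.5),
    0)
  expect_error(
    hho_exploration_move(c(1, 2), 7, 5, 3, sp), "dimension")
})

test_that("soft and hard besiege follow the printed update rules", {
  expect_equal(hho_soft_besiege(c(1, 2), c(3, 4), 0, 1.2), c(2, 2))
  expect_equal(hho_soft_besiege(2, 3, energy = 1, jump = 0), -1)
  expect_equal(hho_hard_besiege(c(1, 2), c(3, 4), 0), c(3, 4))
  expect_equal(hho_hard_besiege(1, 4, 1), 1)
  expect_equal(hho_hard_besiege(0, 2, -0.5), 3)
  # vectorised result equals a component-wise scalar loop
  set.seed(5)
  hawk <- runif(4, -3, 3)
  rabbit <- runif(4, -3, 3)
  vec <- hho_soft_besiege(hawk, rabbit, 0.7, 1.3)
  loop <- vapply(1:4, function(i) hho_soft_besiege(hawk[i], rabbit[i], 0.7, 1.3),
                 numeric(1))
  expect_equal(vec, loop)
})

test_that("soft dive is greedy and spends exactly two evaluations", {
  sp <- search_space(-10, 10, dim = 2)
  sphere <- function(x) sum(x^2)
  # energy 0 makes Y the rabbit, which improves on the hawk
  res <- hho_soft_besiege_dive(c(3, 3), c(1, 1), energy = 0, jump = 1,
                               sphere, sp, fitness = 18)
  expect_equal(res$position, c(1, 1))
  expect_equal(res$fitness, 2)
  expect_equal(res$evals, 2L)
  # both candidates worse: position unchanged
  worse <- function(x) 100
  res2 <- hho_soft_besiege_dive(c(3, 3), c(1, 1), energy = 0, jump = 1,
                                worse, sp, fitness = 18)
  expect_equal(res2$position, c(3, 3))
  expect_equal(res2$fitness, 18)
  expect_equal(res2$evals, 2L)
})

test_that("hard dive anchors on the population mean", {
  sp <- search_space(-10, 10, dim = 2)
  sphere <- function(x) sum(x^2)
  res <- hho_hard_besiege_dive(c(3, 3), c(1, 1), mean_pos = c(2, 2),
                               energy = 0, jump = 1, sphere, sp, fitness = 18)
  expect_equal(res$position, c(1, 1))
  # Y formula equals a component-wise oracle on a random 4-D instance
  set.seed(9)
  hawk <- runif(4)
  rabbit <- runif(4)
  mp <- runif(4)
  e <- 0.3
  j <- 1.4
  y_expected <- vapply(1:4, function(i) rabbit[i] - e * abs(j * rabbit[i] - mp[i]),
                       numeric(1))
  sp4 <- search_space(-10, 10, dim = 4)
  # capture Y by an objective that records its first candidate
  seen <- new.env()
  rec <- function(x) {
    if (is.null(seen$first)) seen$first <- x
    sum(x^2)
  }
  hho_hard_besiege_dive(hawk, rabbit, mp, e, j, rec, sp4, fitness = 0)
  expect_equal(seen$first, y_expected)
})

test_that("population initialisation respects bounds and best-so-far", {
  set.seed(2)
  sp <- search_space(0, 1, dim = 2)
  pop <- hho_init_population(function(x) sum(x^2), sp, 30)
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(pop$rabbit_fitness, min(pop$fitness))
  pop_const <- hho_init_population(function(x) 5, sp, 10)
  expect_equal(pop_const$rabbit_fitness, 5)
  expect_error(hho_init_population(function(x) NaN, sp, 5), "non-finite")
})

test_that("mean position is the per-dimension arithmetic mean", {
  expect_equal(hho_mean_position(rbind(c(0, 0), c(2, 4))), c(1, 2))
  expect_equal(hho_mean_position(matrix(c(3, 7), 1)), c(3, 7))
  set.seed(3)
  m <- matrix(runif(15), 5, 3)
  oracle <- vapply(1:3, function(j) sum(m[, j]) / 5, numeric(1))
  expect_equal(hho_mean_position(m), oracle, tolerance = 1e-15)
  expect_error(hho_mean_position(matrix(numeric(0), 0, 2)), "empty")
})
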