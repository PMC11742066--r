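# Harris Hawks Optimization over a bounded continuous search space.
#
# The population mimics cooperative hawk hunting: a time-decaying escape
# energy E switches each hawk between global exploration (|E| >= 1) and four
# exploitation strategies (soft/hard besiege, with or without Levy-flight
# rapid dives) chosen by E and a fresh uniform draw r. The best position
# found so far is the "rabbit" and is strictly elitist.

#' Bounded continuous search space
#'
#' Describes the box-constrained decision space an optimizer searches.
#' Scalar bounds are recycled to `dim` dimensions.
#'
#' @param lower,upper Numeric vectors of per-dimension bounds. Each
#'   `lower[d]` must be strictly below `upper[d]`.
#' @param dim Number of decision variables. Defaults to the length of the
#'   longer bound vector.
#' @return A `search_space` object: a list with `lower`, `upper`, `dim`.
#' @examples
#' search_space(1, 1000, dim = 2) # hyperparameter box for (C, sigma)
#' @export
search_space <- function(lower, upper, dim = max(length(lower), length(upper))) {
  dim <- check_count(dim, "dim", 1L)
  if (!is.numeric(lower) || !is.numeric(upper)) {
    abort("`lower` and `upper` must be numeric.")
  }
  if (!(length(lower) %in% c(1L, dim)) || !(length(upper) %in% c(1L, dim))) {
    abort("bound vectors must have length 1 or `dim`.")
  }
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("bounds must be finite.")
  }
  if (any(lower >= upper)) abort("`lower` must be < `upper` in every dimension.")
  structure(list(lower = lower, upper = upper, dim = dim),
            class = "search_space")
}

#' Harris Hawks Optimization settings
#'
#' @param n_hawks Population size N (>= 2). Default 30.
#' @param max_iter Iteration budget T (>= 1). Default 50.
#' @param beta Levy-flight exponent in (0, 2]. Default 1.5.
#' @return An `hho_options` object.
#' @export
hho_options <- function(n_hawks = 30, max_iter = 50, beta = 1.5) {
  n_hawks <- check_count(n_hawks, "n_hawks", 2L)
  max_iter <- check_count(max_iter, "max_iter", 1L)
  check_number(beta, "beta", 0, strict = TRUE)
  if (beta > 2) abort("`beta` must be in (0, 2].")
  structure(list(n_hawks = n_hawks, max_iter = max_iter, beta = beta),
            class = "hho_options")
}

clip_to_bounds <- function(x, space) {
  pmin(pmax(x, space$lower), space$upper)
}

#' Mean position of a hawk population
#'
#' Arithmetic mean of the population, per dimension.
#'
#' @param positions An N x D matrix of hawk positions (one row per hawk).
#' @return A length-D numeric vector.
#' @export
hho_mean_position <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) abort("population is empty.")
  colMeans(positions)
}

#' Escape energy of the prey
#'
#' The rabbit's escape energy decays linearly over the iteration budget:
#' `E = 2 * e0 * (1 - t / max_iter)`. Its magnitude drives the switch
#' between exploration (|E| >= 1) and the besiege strategies.
#'
#' @param e0 Initial energy, drawn in (-1, 1) once per hawk per iteration.
#' @param t Current iteration, `0 <= t <= max_iter`.
#' @param max_iter Iteration budget T (>= 1).
#' @return The scalar escape energy.
#' @export
hho_escape_energy <- function(e0, t, max_iter) {
  check_number(e0, "e0")
  check_count(max_iter, "max_iter", 1L)
  check_number(t, "t", 0)
  if (t > max_iter) abort("`t` must be <= `max_iter`.")
  2 * e0 * (1 - t / max_iter)
}

# scale constant of the Levy step at exponent beta
levy_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Levy-flight step vector
#'
#' Heavy-tailed random step used by the progressive rapid dives. Each
#' component is `0.01 * u * sigma / |v|^(1/beta)` with `u`, `v` fresh
#' uniform draws on \[0, 1\] and `sigma` the beta-dependent scale constant.
#' A zero draw of `v` is redrawn so no division by zero can propagate.
#'
#' @param dim Number of components.
#' @param beta Levy exponent (> 0). Default 1.5.
#' @return A length-`dim` numeric step vector.
#' @export
hho_levy_step <- function(dim, beta = 1.5) {
  dim <- check_count(dim, "dim", 1L)
  check_number(beta, "beta", 0, strict = TRUE)
  sigma <- levy_sigma(beta)
  u <- runif(dim)
  v <- runif(dim)
  while (any(v == 0)) v[v == 0] <- runif(sum(v == 0))
  0.01 * u * sigma / abs(v)^(1 / beta)
}

#' Exploration move (random perching)
#'
#' With probability q >= 0.5 the hawk perches relative to a random member
#' of the population; otherwise relative to the rabbit and the population
#' mean, pulled toward a random point of the box. The result is clipped to
#' the bounds. The random draws can be forced for testing.
#'
#' @param hawk,rand_hawk,rabbit,mean_pos Length-D position vectors.
#' @param space A [search_space()].
#' @param q,r1,r2,r3,r4 Optional uniform draws on \[0, 1\]; fresh draws by
#'   default.
#' @return The new length-D position, within bounds.
#' @export
hho_exploration_move <- function(hawk, rand_hawk, rabbit, mean_pos, space,
                                 q = runif(1), r1 = runif(1), r2 = runif(1),
                                 r3 = runif(1), r4 = runif(1)) {
  d <- space$dim
  if (length(hawk) != d || length(rand_hawk) != d ||
      length(rabbit) != d || length(mean_pos) != d) {
    abort("all position vectors must have the space dimension.")
  }
  new <- if (q >= 0.5) {
    rand_hawk - r1 * abs(rand_hawk - 2 * r2 * hawk)
  } else {
    (rabbit - mean_pos) - r3 * (space$lower + r4 * (space$upper - space$lower))
  }
  clip_to_bounds(new, space)
}

#' Soft besiege move
#'
#' The prey still has energy (|E| >= 0.5) and escapes fail (r >= 0.5): the
#' hawk encircles, `X' = (rabbit - hawk) - E * |J * rabbit - hawk|`, with
#' `J` the random jump strength of the rabbit. Bound clipping is the
#' caller's responsibility.
#'
#' @param hawk,rabbit Length-D position vectors.
#' @param energy Escape energy E.
#' @param jump Jump strength J in \[0, 2\].
#' @return The raw (unclipped) new position.
#' @export
hho_soft_besiege <- function(hawk, rabbit, energy, jump) {
  (rabbit - hawk) - energy * abs(jump * rabbit - hawk)
}

#' Hard besiege move
#'
#' The prey is exhausted (|E| < 0.5): `X' = rabbit - E * |rabbit - hawk|`.
#'
#' @inheritParams hho_soft_besiege
#' @return The raw (unclipped) new position.
#' @export
hho_hard_besiege <- function(hawk, rabbit, energy) {
  rabbit - energy * abs(rabbit - hawk)
}

# shared greedy dive: evaluate Y and the Levy dive Z, keep whichever
# strictly improves on the current fitness, else stay put
dive_select <- function(y_cand, hawk, fitness, objective, space, beta) {
  y_cand <- clip_to_bounds(y_cand, space)
  z_cand <- clip_to_bounds(
    y_cand + runif(space$dim) * hho_levy_step(space$dim, beta), space)
  fy <- objective(y_cand)
  fz <- objective(z_cand)
  if (is.finite(fy) && fy < fitness) {
    list(position = y_cand, fitness = fy, evals = 2L)
  } else if (is.finite(fz) && fz < fitness) {
    list(position = z_cand, fitness = fz, evals = 2L)
  } else {
    list(position = hawk, fitness = fitness, evals = 2L)
  }
}

#' Soft besiege with progressive rapid dives
#'
#' When the escape succeeds (r < 0.5) with |E| >= 0.5, the hawk first
#' considers `Y = rabbit - E * |J * rabbit - hawk|`; if that does not
#' improve, a Levy-flight dive `Z = Y + S * LF(D)` is tried. Both
#' candidates are clipped to bounds and evaluated; the hawk keeps its
#' current position when neither improves strictly. Non-finite candidate
#' fitness values are treated as non-improving.
#'
#' @inheritParams hho_soft_besiege
#' @param objective Function mapping a length-D vector to a finite scalar.
#' @param space A [search_space()].
#' @param fitness Current fitness of the hawk.
#' @param beta Levy exponent.
#' @return A list with `position`, `fitness` and the number of objective
#'   `evals` spent (always 2).
#' @export
hho_soft_besiege_dive <- function(hawk, rabbit, energy, jump, objective,
                                  space, fitness, beta = 1.5) {
  y_cand <- rabbit - energy * abs(jump * rabbit - hawk)
  dive_select(y_cand, hawk, fitness, objective, space, beta)
}

#' Hard besiege with progressive rapid dives
#'
#' As [hho_soft_besiege_dive()] but with the first candidate anchored on
#' the population mean: `Y = rabbit - E * |J * rabbit - mean_pos|`.
#'
#' @inheritParams hho_soft_besiege_dive
#' @param mean_pos Population mean position.
#' @export
hho_hard_besiege_dive <- function(hawk, rabbit, mean_pos, energy, jump,
                                  objective, space, fitness, beta = 1.5) {
  y_cand <- rabbit - energy * abs(jump * rabbit - mean_pos)
  dive_select(y_cand, hawk, fitness, objective, space, beta)
}

#' Initialise a hawk population
#'
#' Positions are drawn independently and uniformly within the bounds, the
#' objective is evaluated once per hawk, and the best hawk becomes the
#' rabbit.
#'
#' @param objective Objective function to minimise.
#' @param space A [search_space()].
#' @param n_hawks Population size.
#' @return A list with `positions` (N x D), `fitness` (length N),
#'   `rabbit_position`, `rabbit_fitness`.
#' @export
hho_init_population <- function(objective, space, n_hawks = 30) {
  n_hawks <- check_count(n_hawks, "n_hawks", 1L)
  d <- space$dim
  positions <- matrix(runif(n_hawks * d), n_hawks, d)
  positions <- sweep(positions, 2, space$upper - space$lower, "*")
  positions <- sweep(positions, 2, space$lower, "+")
  fitness <- apply(positions, 1, objective)
  if (any(!is.finite(fitness))) {
    bad <- which(!is.finite(fitness))[1]
    abort(sprintf(
      "objective returned a non-finite value at position (%s).",
      paste(signif(positions[bad, ], 6), collapse = ", ")))
  }
  best <- which.min(fitness)
  list(positions = positions, fitness = fitness,
       rabbit_position = positions[best, ], rabbit_fitness = fitness[best])
}

#' Harris Hawks Optimization
#'
#' Minimises a scalar objective over a box-bounded continuous space. Each
#' iteration, every hawk draws a fresh initial energy `e0` in (-1, 1); the
#' decayed escape energy selects exploration (|E| >= 1) or one of the four
#' besiege strategies, the moved hawk is re-evaluated, and the best-so-far
#' rabbit is updated immediately. All positions are clipped to the bounds
#' before evaluation, so the recorded convergence curve is monotone
#' non-increasing and every visited position is feasible.
#'
#' @param objective Function taking a length-D numeric vector and
#'   returning a finite scalar to minimise.
#' @param space A [search_space()].
#' @param options An [hho_options()] settings object.
#' @param seed Optional integer seed; when supplied the run is fully
#'   deterministic.
#' @return An `hho_result`: list with `best_position`, `best_fitness`,
#'   `convergence` (tibble of per-iteration best-so-far fitness),
#'   `n_evals`, `elapsed` (seconds), plus the inputs.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- hho_optimize(sphere, search_space(-10, 10, dim = 2),
#'                     hho_options(n_hawks = 10, max_iter = 20), seed = 1)
#' res$best_fitness
#' @export
hho_optimize <- function(objective, space, options = hho_options(),
                         seed = NULL) {
  stopifnot(inherits(space, "search_space"), inherits(options, "hho_options"))
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  n <- options$n_hawks
  t_max <- options$max_iter
  beta <- options$beta

  pop <- hho_init_population(objective, space, n)
  positions <- pop$positions
  fitness <- pop$fitness
  rabbit <- pop$rabbit_position
  rabbit_fitness <- pop$rabbit_fitness
  n_evals <- n
  convergence <- numeric(t_max)

  for (t in seq_len(t_max)) {
    mean_pos <- colMeans(positions)
    for (i in seq_len(n)) {
      hawk <- positions[i, ]
      e0 <- 2 * runif(1) - 1
      energy <- 2 * e0 * (1 - t / t_max)
      jump <- 2 * (1 - runif(1))

      if (abs(energy) >= 1) {
        rand_hawk <- positions[sample.int(n, 1L), ]
        cand <- hho_exploration_move(hawk, rand_hawk, rabbit, mean_pos, space)
        f <- objective(cand)
        if (!is.finite(f)) {
          abort(sprintf("objective returned a non-finite value at iteration %d.", t))
        }
        positions[i, ] <- cand
        fitness[i] <- f
        n_evals <- n_evals + 1L
      } else {
        r <- runif(1)
        if (r >= 0.5) {
          cand <- if (abs(energy) >= 0.5) {
            hho_soft_besiege(hawk, rabbit, energy, jump)
          } else {
            hho_hard_besiege(hawk, rabbit, energy)
          }
          cand <- clip_to_bounds(cand, space)
          f <- objective(cand)
          if (!is.finite(f)) {
            abort(sprintf("objective returned a non-finite value at iteration %d.", t))
          }
          positions[i, ] <- cand
          fitness[i] <- f
          n_evals <- n_evals + 1L
        } else {
          step <- if (abs(energy) >= 0.5) {
            hho_soft_besiege_dive(hawk, rabbit, energy, jump, objective,
                                  space, fitness[i], beta)
          } else {
            hho_hard_besiege_dive(hawk, rabbit, mean_pos, energy, jump,
                                  objective, space, fitness[i], beta)
          }
          positions[i, ] <- step$position
          fitness[i] <- step$fitness
          n_evals <- n_evals + step$evals
        }
      }
      if (fitness[i] < rabbit_fitness) {
        rabbit_fitness <- fitness[i]
        rabbit <- positions[i, ]
      }
    }
    convergence[t] <- rabbit_fitness
  }

  structure(list(
    best_position = rabbit,
    best_fitness = rabbit_fitness,
    convergence = tibble(iteration = seq_len(t_max), best_fitness = convergence),
    n_evals = n_evals,
    elapsed = proc.time()[["elapsed"]] - t0,
    space = space, options = options, seed = seed,
    optimizer = "hho"
  ), class = "hho_result")
}

#' Uniform random-search reference optimizer
#'
#' Baseline satisfying the same optimizer contract as [hho_optimize()]:
#' the same total evaluation budget is spent on independent uniform draws.
#'
#' @inheritParams hho_optimize
#' @return An `hho_result` (with `optimizer = "random"`).
#' @export
random_search_optimize <- function(objective, space, options = hho_options(),
                                   seed = NULL) {
  stopifnot(inherits(space, "search_space"), inherits(options, "hho_options"))
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  n <- options$n_hawks
  t_max <- options$max_iter
  pop <- hho_init_population(objective, space, n)
  best <- pop$rabbit_position
  best_fitness <- pop$rabbit_fitness
  n_evals <- n
  convergence <- numeric(t_max)
  for (t in seq_len(t_max)) {
    cand <- matrix(runif(n * space$dim), n, space$dim)
    cand <- sweep(cand, 2, space$upper - space$lower, "*")
    cand <- sweep(cand, 2, space$lower, "+")
    f <- apply(cand, 1, objective)
    n_evals <- n_evals + n
    k <- which.min(f)
    if (f[k] < best_fitness) {
      best_fitness <- f[k]
      best <- cand[k, ]
    }
    convergence[t] <- best_fitness
  }
  structure(list(
    best_position = best, best_fitness = best_fitness,
    convergence = tibble(iteration = seq_len(t_max), best_fitness = convergence),
    n_evals = n_evals,
    elapsed = proc.time()[["elapsed"]] - t0,
    space = space, options = options, seed = seed,
    optimizer = "random"
  ), class = "hho_result")
}

#' Look up a registered optimizer by name
#'
#' The plug-in contract is `function(objective, space, options, seed)`
#' returning an `hho_result`-shaped object, so third-party metaheuristics
#' can be benchmarked side by side.
#'
#' @param name `"hho"`, `"random"`, or a function obeying the contract.
#' @return The optimizer function.
#' @export
get_optimizer <- function(name) {
  if (is.function(name)) return(name)
  switch(as.character(name),
    hho = hho_optimize,
    random = random_search_optimize,
    abort(sprintf("unknown optimizer '%s' (registered: hho, random).", name))
  )
}

#' @export
print.hho_result <- function(x, ...) {
  cat(sprintf("<%s optimization result>\n", x$optimizer))
  cat(sprintf("  best fitness: %.6g after %d evaluations (%.2fs)\n",
              x$best_fitness, x$n_evals, x$elapsed))
  cat(sprintf("  best position: (%s)\n",
              paste(signif(x$best_position, 6), collapse = ", ")))
  invisible(x)
}

#' @rdname hho_optimize
#' @param x An `hho_result`.
#' @param ... Unused.
#' @method tidy hho_result
#' @export
tidy.hho_result <- function(x, ...) {
  tibble(term = paste0("x", seq_along(x$best_position)),
         estimate = as.numeric(x$best_position))
}

#' @rdname hho_optimize
#' @method glance hho_result
#' @export
glance.hho_result <- function(x, ...) {
  tibble(best_fitness = x$best_fitness, n_evals = x$n_evals,
         iterations = nrow(x$convergence), elapsed = x$elapsed,
         optimizer = x$optimizer)
}

#' @rdname hho_optimize
#' @param object An `hho_result`.
#' @method autoplot hho_result
#' @export
autoplot.hho_result <- function(object, ...) {
  ggplot2::ggplot(object$convergence,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::labs(x = "Iteration", y = "Best objective so far",
                  title = sprintf("%s convergence", toupper(object$optimizer))) +
    ggplot2::theme_minimal()
}
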