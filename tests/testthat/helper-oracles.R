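# Independent oracles used to cross-check the package's own computations.

# gamma function via adaptive quadrature, independent of base::gamma
gamma_numeric <- function(z) {
  stats::integrate(function(t) t^(z - 1) * exp(-t), 0, Inf,
                   rel.tol = 1e-13, abs.tol = 0)$value
}

# Levy scale constant recomputed with the quadrature gamma
levy_sigma_oracle <- function(beta) {
  (gamma_numeric(1 + beta) * sin(pi * beta / 2) /
     (gamma_numeric((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

# average within-row ranks by explicit counting (no call to rank())
ranks_by_counting <- function(row) {
  k <- length(row)
  vapply(seq_len(k), function(j) {
    smaller <- sum(row < row[j])
    equal <- sum(row == row[j])
    # positions smaller+1 .. smaller+equal are shared; average them
    smaller + (equal + 1) / 2
  }, numeric(1))
}

# Friedman chi-square from first principles (loop-based ranking)
friedman_oracle <- function(m, tie_correction = TRUE) {
  n <- nrow(m)
  k <- ncol(m)
  ranks <- t(apply(m, 1, ranks_by_counting))
  rj <- colSums(ranks)
  chi <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  if (tie_correction) {
    tie_sum <- 0
    for (i in seq_len(n)) {
      for (v in unique(m[i, ])) {
        t_v <- sum(m[i, ] == v)
        tie_sum <- tie_sum + t_v^3 - t_v
      }
    }
    corr <- 1 - tie_sum / (n * k * (k^2 - 1))
    chi <- if (corr <= 0) 0 else chi / corr
  }
  chi
}

# chi-square upper tail by numeric integration of the density
chisq_tail_numeric <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma_numeric(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-12)$value
}

# brute-force convex-program oracle for the SVR dual: interior-point QP
# over z = (alpha, alpha*) with the balance and box constraints
svr_dual_oracle <- function(x, y, C, sigma, epsilon) {
  stopifnot(requireNamespace("kernlab", quietly = TRUE))
  x <- as.matrix(x)
  l <- length(y)
  kmat <- exp(-as.matrix(stats::dist(x))^2 / (2 * sigma^2))
  s <- c(rep(-1, l), rep(1, l))
  big_k <- kmat[c(seq_len(l), seq_len(l)), c(seq_len(l), seq_len(l))]
  h <- outer(s, s) * big_k + diag(1e-12, 2 * l)
  cc <- epsilon - s * rep(y, 2)
  sol <- kernlab::ipop(c = matrix(cc), H = h, A = matrix(s, 1), b = 0,
                       l = matrix(rep(0, 2 * l)), u = matrix(rep(C, 2 * l)),
                       r = 0, sigf = 12, maxiter = 200)
  z <- kernlab::primal(sol)
  beta <- z[(l + 1):(2 * l)] - z[seq_len(l)]
  obj <- 0.5 * drop(beta %*% kmat %*% beta) + epsilon * sum(abs(beta)) -
    sum(y * beta)
  unbounded <- which(abs(beta) > 1e-6 * C & abs(beta) < C * (1 - 1e-6))
  bias <- if (length(unbounded) > 0) {
    mean(y[unbounded] - (kmat %*% beta)[unbounded] -
           sign(beta[unbounded]) * epsilon)
  } else {
    NA_real_
  }
  list(beta = beta, dual_objective = obj, bias = bias, kmat = kmat)
}

# random small SVR regression toy
random_svr_toy <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  d <- sample(1:3, 1)
  list(
    x = matrix(runif(n * d, -2, 2), n),
    y = runif(n, -1, 2),
    C = runif(1, 0.5, 20),
    sigma = runif(1, 0.3, 3),
    epsilon = 0.05
  )
}

# published Friedman comparison values for the county datasets
published_friedman_p <- c(`1001` = 2.704e-12, `1003` = 5.877e-11,
                          `1005` = 3.743e-12, `1007` = 3.239e-08,
                          `1009` = 7.279e-12)
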