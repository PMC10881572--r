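# Independent oracles, deliberately written through different representations
# than the package code paths they check.

# E[X^r] through the quantile representation: E[X^r] = int_0^1 Q(u)^r du,
# with Q written directly from the closed form (no shared helpers).
oracle_moment <- function(r, alpha, theta) {
  Q <- function(u) log(1 + 2 / (-log(u))^(1 / alpha)) / theta
  integrate(function(u) Q(u)^r, 0, 1, rel.tol = 1e-11,
            subdivisions = 500L)$value
}

# partial moment int_0^y x^r f(x) dx by quadrature on the density written out
# in its raw (non-log) closed form
oracle_partial_moment <- function(r, y, alpha, theta) {
  f <- function(x) {
    g <- 2 * exp(-theta * x) / (1 - exp(-theta * x))
    alpha * theta * (2 * exp(-theta * x))^alpha /
      (1 - exp(-theta * x))^(alpha + 1) * exp(-g^alpha)
  }
  integrate(function(x) x^r * f(x), 0, y, rel.tol = 1e-11,
            subdivisions = 500L)$value
}

# central finite differences of the negative log-likelihood
oracle_fd_score <- function(x, alpha, theta, h = 1e-6) {
  c(alpha = (ofhl_nll(x, alpha + h, theta) - ofhl_nll(x, alpha - h, theta)) / (2 * h),
    theta = (ofhl_nll(x, alpha, theta + h) - ofhl_nll(x, alpha, theta - h)) / (2 * h))
}

# brute-force re-summations of the objectives with explicit loops and the
# plain (non-log-space) CDF
oracle_cdf <- function(x, alpha, theta)
  exp(-(2 * exp(-theta * x) / (1 - exp(-theta * x)))^alpha)

oracle_ad <- function(x, alpha, theta) {
  xs <- sort(x); n <- length(xs)
  s <- 0
  for (k in seq_len(n)) {
    s <- s + (2 * k - 1) * (log(oracle_cdf(xs[k], alpha, theta)) +
                            log(1 - oracle_cdf(xs[n + 1 - k], alpha, theta)))
  }
  -n - s / n
}

oracle_cvm <- function(x, alpha, theta) {
  xs <- sort(x); n <- length(xs)
  s <- 1 / (12 * n)
  for (k in seq_len(n))
    s <- s + (oracle_cdf(xs[k], alpha, theta) - (2 * k - 1) / (2 * n))^2
  s
}

oracle_mps <- function(x, alpha, theta) {
  xs <- sort(x); n <- length(xs)
  F <- c(0, oracle_cdf(xs, alpha, theta), 1)
  s <- 0
  for (k in seq_len(n + 1)) s <- s + log(F[k + 1] - F[k])
  s / (n + 1)
}

oracle_ls <- function(x, alpha, theta, weighted) {
  xs <- sort(x); n <- length(xs)
  s <- 0
  for (k in seq_len(n)) {
    w <- if (weighted) (n + 1)^2 * (n + 2) / (k * (n - k + 1)) else 1
    s <- s + w * (oracle_cdf(xs[k], alpha, theta) - k / (n + 1))^2
  }
  s
}

# parameter grid shared by the property tests
ofhl_test_grid <- expand.grid(alpha = c(0.25, 0.5, 1, 1.5, 3),
                              theta = c(0.5, 1, 2))
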