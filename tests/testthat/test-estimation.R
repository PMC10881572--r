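covid <- ofhl_data("covid_mexico")
surv <- ofhl_data("chemo_survival")

test_that("negative log-likelihood matches the printed fixture values and the density", {
  expect_equal(ofhl_nll(covid, 1.0083, 0.2807), 266.453, tolerance = 1e-5)
  expect_equal(ofhl_nll(surv, 0.4835, 1.7273), 56.8353, tolerance = 1e-5)
  set.seed(5)
  x <- rofhl(40, 1.2, 0.8)
  expect_equal(ofhl_nll(x, 0.9, 1.1), -sum(dofhl(x, 0.9, 1.1, log = TRUE)),
               tolerance = 1e-12)
  # single observation at its own median
  m <- ofhl_median(1, 1)
  expect_equal(ofhl_nll(m, 1, 1), -dofhl(m, 1, 1, log = TRUE), tolerance = 1e-12)
  # +Inf sentinel, not NaN or an error, when a log term degenerates
  # (x so small that 1 - exp(-theta*x) rounds to 0)
  expect_identical(ofhl_nll(1e-320, 1, 1), Inf)
})

test_that("score equals finite differences of the likelihood and vanishes at the MLE", {
  set.seed(6)
  for (rep in 1:25) {
    x <- rofhl(sample(10:60, 1), runif(1, 0.4, 2.5), runif(1, 0.4, 2.5))
    a <- runif(1, 0.4, 2.5); t <- runif(1, 0.4, 2.5)
    sc <- ofhl_score(x, a, t)
    fd <- oracle_fd_score(x, a, t)
    expect_equal(unname(sc), unname(fd),
                 tolerance = 1e-6 * max(1, max(abs(fd))))
  }
  # hand-derived single-point check at x = 1, alpha = theta = 1:
  # g = 2e/(e-1) ... evaluated numerically from the closed-form derivatives
  g1 <- 2 * exp(-1) / (1 - exp(-1))
  d_alpha <- -(1 + log(g1) - g1 * log(g1))
  d_theta <- -(1 - 1 / (1 - exp(-1)) - exp(-1) / (1 - exp(-1)) +
                 g1 / (1 - exp(-1)))
  expect_equal(unname(ofhl_score(1, 1, 1)), c(d_alpha, d_theta),
               tolerance = 1e-12)
  # stationarity at the fitted optimum, at the optimiser's value tolerance
  fit <- ofhl_fit(covid, "mle")
  expect_lt(max(abs(ofhl_score(covid, fit$alpha, fit$theta))), 5e-3)
})

test_that("objectives equal independent brute-force re-summations", {
  set.seed(7)
  for (rep in 1:15) {
    x <- rofhl(sample(8:40, 1), runif(1, 0.4, 2.5), runif(1, 0.4, 2.5))
    a <- runif(1, 0.4, 2.5); t <- runif(1, 0.4, 2.5)
    expect_equal(ofhl_ad_objective(x, a, t), oracle_ad(x, a, t), tolerance = 1e-12)
    expect_equal(ofhl_cvm_objective(x, a, t), oracle_cvm(x, a, t), tolerance = 1e-12)
    expect_equal(ofhl_mps_objective(x, a, t), oracle_mps(x, a, t), tolerance = 1e-12)
    expect_equal(ofhl_ls_objective(x, a, t, FALSE), oracle_ls(x, a, t, FALSE),
                 tolerance = 1e-12)
    expect_equal(ofhl_ls_objective(x, a, t, TRUE), oracle_ls(x, a, t, TRUE),
                 tolerance = 1e-12)
  }
})

test_that("objectives attain their structural minima on constructed samples", {
  n <- 25; a <- 1.3; t <- 0.7; k <- seq_len(n)
  # CDF values landing exactly on (2k-1)/(2n) minimise the CvM criterion
  x_cvm <- qofhl((2 * k - 1) / (2 * n), a, t)
  expect_equal(ofhl_cvm_objective(x_cvm, a, t), 1 / (12 * n), tolerance = 1e-12)
  # AD statistic near its floor for the same probability-uniform construction
  x_ad <- qofhl((k - 0.5) / n, a, t)
  expect_lt(ofhl_ad_objective(x_ad, a, t), 0.3)
  # CDF values landing on k/(n+1) zero the least-squares criteria
  x_ls <- qofhl(k / (n + 1), a, t)
  expect_equal(ofhl_ls_objective(x_ls, a, t, FALSE), 0, tolerance = 1e-14)
  expect_equal(ofhl_ls_objective(x_ls, a, t, TRUE), 0, tolerance = 1e-11)
  # spacings telescope to 1 at arbitrary parameters
  set.seed(8)
  x <- rofhl(30, 1, 1)
  F <- c(0, pofhl(sort(x), 2.2, 0.4), 1)
  expect_equal(sum(diff(F)), 1, tolerance = 1e-12)
  # n = 1 mean log spacing is the symmetric two-piece form
  expect_equal(ofhl_mps_objective(2, 1.1, 0.6),
               (log(pofhl(2, 1.1, 0.6)) + log(1 - pofhl(2, 1.1, 0.6))) / 2,
               tolerance = 1e-14)
  # tied observations fall back to the density surrogate instead of -Inf
  xt <- c(0.5, 1, 1, 2)
  expect_true(is.finite(ofhl_mps_objective(xt, 1, 1)))
})

test_that("objective values at the published estimates are reproduced", {
  # frozen against the brute-force oracles; the AD objective at the ADE
  # optimum is 0.3286 (the comparison tables' A* column is a different,
  # composite-normality statistic -- see the gof tests)
  expect_equal(ofhl_ad_objective(covid, 1.0020, 0.2749), 0.328578, tolerance = 1e-4)
  expect_equal(ofhl_ad_objective(covid, 1.0020, 0.2749),
               oracle_ad(covid, 1.0020, 0.2749), tolerance = 1e-12)
  expect_equal(ofhl_cvm_objective(covid, 0.9878, 0.2734), 0.044836, tolerance = 1e-4)
  expect_equal(ofhl_ls_objective(covid, 0.9737, 0.2741, FALSE), 0.041794,
               tolerance = 1e-4)
})

test_that("all six methods reproduce the published covid estimates", {
  printed <- list(mle = c(1.0083, 0.2807), ade = c(1.0020, 0.2749),
                  cvme = c(0.9878, 0.2734), mpse = c(0.9672, 0.2824),
                  olse = c(0.9737, 0.2741), wlse = c(0.9985, 0.2753))
  for (m in names(printed)) {
    f <- ofhl_fit(covid, m)
    expect_true(f$converged)
    expect_equal(unname(coef(f)), printed[[m]], tolerance = 5e-3)
    expect_equal(f$nll, ofhl_nll(covid, f$alpha, f$theta), tolerance = 1e-10)
  }
  fs <- ofhl_fit(surv, "mle")
  expect_equal(unname(coef(fs)), c(0.4835, 1.7273), tolerance = 1e-3)
  expect_equal(ofhl_fit(surv, "cvme")$theta, 1.8668, tolerance = 1e-3)
})

test_that("each method recovers the truth from a large simulated sample", {
  x <- rofhl(5000, 1.5, 0.5, seed = 99)
  for (m in c("mle", "ade", "cvme", "mpse", "olse", "wlse")) {
    f <- ofhl_fit(x, m)
    expect_lt(abs(f$alpha - 1.5), 0.1)
    expect_lt(abs(f$theta - 0.5), 0.1)
  }
})

test_that("the optimum is invariant to the optimisation parameterisation", {
  f <- ofhl_fit(covid, "mle")
  nat <- optim(c(1, log(3) / median(covid)),
               function(p) ofhl_nll(covid, p[1], p[2]),
               method = "L-BFGS-B", lower = c(1e-8, 1e-8),
               control = list(factr = 1e3))
  expect_equal(unname(coef(f)), nat$par, tolerance = 1e-5)
})
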