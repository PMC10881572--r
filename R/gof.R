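# Goodness-of-fit battery: information criteria, Anderson-Darling and
# Cramer-von Mises statistics (two reporting conventions, see below), the
# Kolmogorov-Smirnov test and the scaled total-time-on-test transform.
#
# Two AD/CvM conventions coexist deliberately.  `ad_stat`/`cvm_stat` are the
# direct statistics of the fitted CDF — identical formulas to the estimation
# objectives.  `a_star`/`w_star` are the composite-normality variants
# obtained by mapping the fitted CDF values to normal scores
# z = qnorm(F(x)) and applying the modified AD/CvM normality tests with
# estimated mean and sd (the convention behind the A*/W* columns of the
# standard lifetime-distribution comparison tables, e.g. R's nortest tests
# applied to the probability-integral transform).  A perfectly specified
# model makes z standard normal, so both detect misfit, but the composite
# version absorbs location/scale misfit and is numerically much smaller for
# badly fitting models.

#' Information criteria from a negative log-likelihood
#'
#' @param neg_ll negative maximised log-likelihood.
#' @param k_params number of free parameters.
#' @param n sample size; must exceed `k_params + 1` (CAIC correction).
#' @return A list with `aic`, `sic`, `caic`, `hqic`:
#'   \eqn{AIC = 2k + 2(-L)}, \eqn{SIC = k\log n + 2(-L)},
#'   \eqn{CAIC = AIC + 2k(k+1)/(n-k-1)},
#'   \eqn{HQIC = 2k\log(\log n) + 2(-L)}.
#' @examples
#' information_criteria(266.453, 2, 108)$aic  # ~536.906
#' @export
information_criteria <- function(neg_ll, k_params, n) {
  stopifnot(is.numeric(neg_ll), length(neg_ll) == 1L,
            k_params >= 1, n >= 1)
  if (n <= k_params + 1)
    stop("CAIC is undefined for n <= k_params + 1", call. = FALSE)
  aic <- 2 * k_params + 2 * neg_ll
  list(aic = aic,
       sic = k_params * log(n) + 2 * neg_ll,
       caic = aic + 2 * k_params * (k_params + 1) / (n - k_params - 1),
       hqic = 2 * k_params * log(log(n)) + 2 * neg_ll)
}

# shared: sorted sample + fitted CDF values with basic checks
.gof_pit <- function(x, cdf_fn) {
  xs <- .ofhl_check_sample(x)
  u <- cdf_fn(xs)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("'cdf_fn' must return values in [0, 1] for all sample points",
         call. = FALSE)
  list(xs = xs, u = u, n = length(xs))
}

#' Composite-normality A* and W* statistics of a fitted CDF
#'
#' The A*/W* reporting convention of lifetime-distribution comparison
#' tables: the fitted CDF values are mapped to normal scores
#' `z = qnorm(cdf_fn(x))` and the small-sample-modified Anderson-Darling
#' (`pit_ad_star`) or Cramer-von Mises (`pit_cvm_star`) normality statistic
#' with estimated mean and sd is returned, i.e.
#' \eqn{A^* = A (1 + 0.75/n + 2.25/n^2)} and \eqn{W^* = W (1 + 0.5/n)}.
#'
#' For the *direct* statistics of the fitted CDF use
#' [ofhl_ad_objective()] / [ofhl_cvm_objective()] (or `ad_stat` / `cvm_stat`
#' in [gof_report()]), which are the same formulas the minimum-distance
#' estimators optimise.
#'
#' @param x positive sample.
#' @param cdf_fn vectorised fitted CDF.
#' @return The modified statistic, a positive number.
#' @examples
#' x <- ofhl_data("covid_mexico")
#' pit_ad_star(x, function(q) pofhl(q, 1.0083, 0.2807))  # ~0.3623
#' @export
pit_ad_star <- function(x, cdf_fn) {
  g <- .gof_pit(x, cdf_fn)
  z <- qnorm(g$u)
  p <- pnorm((z - mean(z)) / sd(z))
  k <- seq_len(g$n)
  A <- -g$n - mean((2 * k - 1) * (log(p) + log(1 - rev(p))))
  A * (1 + 0.75 / g$n + 2.25 / g$n^2)
}

#' @rdname pit_ad_star
#' @export
pit_cvm_star <- function(x, cdf_fn) {
  g <- .gof_pit(x, cdf_fn)
  z <- qnorm(g$u)
  p <- pnorm((z - mean(z)) / sd(z))
  k <- seq_len(g$n)
  W <- sum((p - (2 * k - 1) / (2 * g$n))^2) + 1 / (12 * g$n)
  W * (1 + 0.5 / g$n)
}

#' One-sample Kolmogorov-Smirnov test against a fitted CDF
#'
#' The two-sided statistic
#' \eqn{D = \max_k \max(|k/n - F(x_{(k)})|, |(k-1)/n - F(x_{(k)})|)} with a
#' p-value from the exact distribution of D (for `n < 100`, the R
#' convention) or from the asymptotic Kolmogorov series
#' \eqn{Q(\lambda) = 2\sum_{j\ge1} (-1)^{j-1} e^{-2j^2\lambda^2}},
#' \eqn{\lambda = \sqrt{n} D}, truncated at `1e-12`.
#'
#' @inheritParams pit_ad_star
#' @param exact logical; exact p-value. Defaults to `n < 100`.
#' @return A list with `statistic` and `p_value`.
#' @examples
#' ks_test_cdf(ofhl_data("chemo_survival"),
#'             function(q) pofhl(q, 0.4835, 1.7273))  # D ~0.1005, p ~0.7155
#' @export
ks_test_cdf <- function(x, cdf_fn, exact = NULL) {
  g <- .gof_pit(x, cdf_fn)
  k <- seq_len(g$n)
  D <- max(pmax(abs(k / g$n - g$u), abs((k - 1) / g$n - g$u)))
  if (is.null(exact)) exact <- g$n < 100
  p <- if (exact && !anyDuplicated(g$xs)) {
    # exact distribution of D via the standard one-sample machinery
    suppressWarnings(stats::ks.test(g$xs, cdf_fn, exact = TRUE)$p.value)
  } else {
    kolmogorov_pvalue(D, g$n)
  }
  list(statistic = D, p_value = min(1, max(0, p)))
}

#' Asymptotic Kolmogorov p-value
#'
#' \eqn{P(\sqrt{n} D > \lambda) \approx 2\sum_{j\ge1}(-1)^{j-1}
#' e^{-2 j^2 \lambda^2}}, summed until terms fall below `1e-12`.
#'
#' @param D two-sided KS statistic.
#' @param n sample size.
#' @return The upper-tail probability in \[0, 1\].
#' @export
kolmogorov_pvalue <- function(D, n) {
  lambda <- sqrt(n) * D
  if (lambda < 1e-8) return(1)
  total <- 0
  for (j in 1:1000) {
    term <- (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-12) break
  }
  min(1, max(0, 2 * total))
}

#' Goodness-of-fit report for a fitted CDF
#'
#' Assembles the full battery for one fitted model on one sample:
#' information criteria from `neg_ll` and `k_params`, the direct
#' Anderson-Darling and Cramer-von Mises statistics of the fitted CDF
#' (`ad_stat`, `cvm_stat` — identical formulas to the estimation
#' objectives), the composite-normality `a_star`/`w_star` variants used in
#' the comparison tables, and the Kolmogorov-Smirnov statistic and p-value.
#'
#' @inheritParams pit_ad_star
#' @param neg_ll negative log-likelihood of the fitted model on `x`.
#' @param k_params number of fitted parameters.
#' @param exact passed to [ks_test_cdf()].
#' @return An object of class `"ofhl_gof"`: a list with `n`, `k_params`,
#'   `neg_ll`, `aic`, `sic`, `caic`, `hqic`, `ad_stat`, `cvm_stat`,
#'   `a_star`, `w_star`, `ks`, `ks_pvalue`.
#' @export
gof_report <- function(x, cdf_fn, neg_ll, k_params, exact = NULL) {
  g <- .gof_pit(x, cdf_fn)
  ic <- information_criteria(neg_ll, k_params, g$n)
  k <- seq_len(g$n)
  # direct statistics (same formulas as the estimation objectives)
  lF <- base::log(g$u)
  lS <- log1p(-g$u)
  ad <- -g$n - mean((2 * k - 1) * (lF + rev(lS)))
  cvm <- 1 / (12 * g$n) + sum((g$u - (2 * k - 1) / (2 * g$n))^2)
  ks <- ks_test_cdf(g$xs, cdf_fn, exact = exact)
  structure(list(
    n = g$n, k_params = k_params, neg_ll = neg_ll,
    aic = ic$aic, sic = ic$sic, caic = ic$caic, hqic = ic$hqic,
    ad_stat = ad, cvm_stat = cvm,
    a_star = pit_ad_star(g$xs, cdf_fn),
    w_star = pit_cvm_star(g$xs, cdf_fn),
    ks = ks$statistic, ks_pvalue = ks$p_value), class = "ofhl_gof")
}

#' Goodness of fit of the OFHL or half-logistic model
#'
#' Convenience wrapper around [gof_report()]: evaluates the battery for an
#' OFHL fit (`model = "ofhl"`, parameters `alpha`, `theta`, `k_params = 2`)
#' or the half-logistic baseline (`model = "hl"`, parameter `theta`,
#' `k_params = 1`) at explicitly supplied parameters — the comparison tables
#' evaluate each estimation method at its own estimates, so no refitting is
#' hidden here. A fitted [ofhl_fit()] object can be given instead of
#' parameters.
#'
#' @param x positive sample.
#' @param fit an `"ofhl_fit"` object, or `NULL` if parameters are given.
#' @param alpha,theta parameters (ignored when `fit` is supplied).
#' @param model `"ofhl"` or `"hl"`.
#' @param exact passed to [ks_test_cdf()].
#' @return An `"ofhl_gof"` object.
#' @examples
#' x <- ofhl_data("covid_mexico")
#' ofhl_gof(x, ofhl_fit(x, "mle"))
#' @export
ofhl_gof <- function(x, fit = NULL, alpha = NULL, theta = NULL,
                     model = c("ofhl", "hl"), exact = NULL) {
  model <- match.arg(model)
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "ofhl_fit"))
    if (is.na(fit$alpha)) model <- "hl"
    alpha <- fit$alpha
    theta <- fit$theta
  }
  if (model == "ofhl") {
    stopifnot(!is.null(alpha), !is.null(theta))
    gof_report(x, function(q) pofhl(q, alpha, theta),
               neg_ll = ofhl_nll(x, alpha, theta), k_params = 2L, exact = exact)
  } else {
    stopifnot(!is.null(theta))
    gof_report(x, function(q) phl(q, theta),
               neg_ll = -sum(dhl(.ofhl_check_sample(x), theta, log = TRUE)),
               k_params = 1L, exact = exact)
  }
}

#' @export
print.ofhl_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit (n = %d, k = %d)\n", x$n, x$k_params))
  cat(sprintf("  -log L = %.4f | AIC %.4f  SIC %.4f  CAIC %.4f  HQIC %.4f\n",
              x$neg_ll, x$aic, x$sic, x$caic, x$hqic))
  cat(sprintf("  A* %.4f  W* %.4f  (direct AD %.4f, CvM %.4f)\n",
              x$a_star, x$w_star, x$ad_stat, x$cvm_stat))
  cat(sprintf("  KS %.4f (p = %.4f)\n", x$ks, x$ks_pvalue))
  invisible(x)
}

#' Scaled total-time-on-test transform
#'
#' The TTT curve of a sorted sample:
#' \eqn{T(r/n) = [\sum_{i \le r} x_{(i)} + (n-r) x_{(r)}] / \sum_i x_{(i)}}
#' for `r = 0, ..., n`, running from (0,0) to (1,1) and non-decreasing. A
#' concave curve indicates increasing hazard, convex decreasing, S-shapes
#' bathtub forms — the standard diagnostic before fitting a lifetime model.
#'
#' @param x positive sample, `n >= 2`.
#' @return A `data.frame` with columns `u = r/n` and `T`.
#' @examples
#' head(ttt_curve(ofhl_data("chemo_survival")))
#' @export
ttt_curve <- function(x) {
  xs <- .ofhl_check_sample(x, min_n = 2L)
  n <- length(xs)
  r <- seq_len(n)
  T <- (cumsum(xs) + (n - r) * xs) / sum(xs)
  data.frame(u = c(0, r / n), T = c(0, T))
}
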