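# Moment machinery: the double-series expansion of the OFHL density and the
# quantities built on it (raw, incomplete and conditional moments, MGF, mean
# residual life, mean waiting time).
#
# The expansion writes f(x) = alpha*theta * sum_{k,l} eta_{k,l} 2^{alpha(k+1)}
# exp(-theta x (alpha(k+1)+l)) with eta_{k,l} = (-1)^k/k! * C(alpha k+alpha+l, l).
# Term-by-term integration gives the r-th raw moment
#   E[X^r] = alpha * sum_{k,l} eta_{k,l} 2^{alpha(k+1)}
#            / (alpha(k+1)+l)^{r+1} * Gamma(r+1) / theta^r.
# This rearranged series is only *formally* convergent: for alpha(k+1) > r the
# inner l-sum diverges, and summed k-first it converges conditionally with
# severe cancellation. In practice the truncated sum is accurate for small
# alpha (<= ~0.5) and detectably divergent otherwise, so every series-based
# function takes method = "auto" (series with quadrature fallback), "series"
# (fails loudly with the partial sum) or "quadrature".

#' Truncation control for the OFHL moment series
#'
#' @param k_max outer truncation of the alternating index `k` (>= 1).
#' @param l_max inner truncation of the binomial index `l` (>= 1).
#' @param rel_tol positive early-stop tolerance: the sweep over `k` at fixed
#'   `l` stops the summation once three consecutive sweeps each contribute
#'   less than `rel_tol` of the running total.
#' @return A list with class `"ofhl_series_control"`.
#' @export
ofhl_series_control <- function(k_max = 60, l_max = 400, rel_tol = 1e-10) {
  stopifnot(k_max >= 1, l_max >= 1, rel_tol > 0, rel_tol < 1)
  structure(list(k_max = as.integer(k_max), l_max = as.integer(l_max),
                 rel_tol = rel_tol), class = "ofhl_series_control")
}

.ofhl_nonconv <- function(what, partial, control) {
  stop(errorCondition(
    sprintf(paste0("OFHL series for %s did not converge within (k_max = %d, ",
                   "l_max = %d); partial sum %.6g. The expansion is only ",
                   "formally convergent for larger alpha; use method = ",
                   "\"quadrature\" (or the default \"auto\")."),
            what, control$k_max, control$l_max, partial),
    class = c("ofhl_nonconvergence", "error", "condition"),
    partial = partial))
}

# Core truncated double sum: sum_{k,l} eta_{k,l} 2^{a(k+1)} w(a(k+1)+l) where
# the weight function w(c) is supplied (vectorised over c).  Sums k in full at
# each l (the only ordering under which the series semi-converges), stops after
# three consecutive l-sweeps below rel_tol, and flags both budget exhaustion
# and floating-point cancellation (peak term magnitude swamping the total).
.ofhl_series_sum <- function(alpha, weight_fn, control, what) {
  kvec <- 0:control$k_max
  ak <- alpha * (kvec + 1)
  sgn <- (-1)^kvec
  lbase <- -lfactorial(kvec) + ak * log(2) - lgamma(ak + 1)
  total <- 0; peak <- 0; n_small <- 0
  for (l in 0:control$l_max) {
    lterm <- exp(lbase + lgamma(ak + l + 1) - lgamma(l + 1))
    term <- sgn * lterm * weight_fn(ak + l)
    sweep <- sum(term)
    if (!is.finite(sweep)) .ofhl_nonconv(what, total, control)
    peak <- max(peak, max(abs(term)))
    total <- total + sweep
    if (l >= 5 && abs(sweep) < control$rel_tol * abs(total)) {
      n_small <- n_small + 1
      if (n_small >= 3) {
        if (peak * .Machine$double.eps > abs(total) * 1e-6)
          .ofhl_nonconv(what, total, control)  # precision lost to cancellation
        return(total)
      }
    } else n_small <- 0
  }
  .ofhl_nonconv(what, total, control)
}

.ofhl_quad_moment <- function(r, alpha, theta) {
  integrate(function(x) x^r * dofhl(x, alpha, theta), 0, Inf,
            rel.tol = 1e-10, subdivisions = 400L)$value
}

.ofhl_check_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 1 || r != round(r))
    stop("'r' must be a positive integer (non-integer moments are not supported)",
         call. = FALSE)
  as.integer(r)
}

#' Raw moments of the OFHL distribution
#'
#' Computes \eqn{E[X^r]} either from the truncated double-series expansion of
#' the density or by adaptive quadrature of \eqn{x^r f(x)}.
#'
#' The series is only formally convergent: summed with the alternating index
#' innermost it is accurate for small `alpha` but suffers catastrophic
#' cancellation as `alpha` grows. `method = "series"` therefore raises an
#' error of class `"ofhl_nonconvergence"` (carrying the partial sum in its
#' `partial` field) when the truncation budget is exhausted or precision is
#' lost; the default `"auto"` falls back to quadrature in that case.
#'
#' @param r positive integer moment order.
#' @param alpha,theta positive shape parameters.
#' @param method `"auto"`, `"series"` or `"quadrature"`.
#' @param control a [ofhl_series_control()] list.
#' @return The moment \eqn{E[X^r]}, a positive number.
#' @examples
#' ofhl_moment(1, 0.25, 0.75)
#' @export
ofhl_moment <- function(r, alpha, theta,
                        method = c("auto", "series", "quadrature"),
                        control = ofhl_series_control()) {
  method <- match.arg(method)
  .ofhl_check_params(alpha, theta)
  r <- .ofhl_check_r(r)
  if (method == "quadrature") return(.ofhl_quad_moment(r, alpha, theta))
  series <- function()
    alpha * gamma(r + 1) / theta^r *
      .ofhl_series_sum(alpha, function(c) c^(-(r + 1)), control,
                       sprintf("E[X^%d]", r))
  if (method == "series") return(series())
  tryCatch(series(), ofhl_nonconvergence = function(e)
    .ofhl_quad_moment(r, alpha, theta))
}

#' Moment generating function of the OFHL distribution
#'
#' Maclaurin sum \eqn{M_X(t) = \sum_r t^r E[X^r] / r!} with the raw moments
#' from [ofhl_moment()]. The right tail of the density decays like
#' \eqn{e^{-\alpha\theta x}} for \eqn{\alpha \le 1} (and faster otherwise), so
#' `t` is rejected at or beyond the conservative bound
#' \eqn{\theta \min(\alpha, 1)}.
#'
#' @param t evaluation point, `t < theta * min(alpha, 1)`.
#' @inheritParams ofhl_moment
#' @param max_terms Maclaurin truncation.
#' @return \eqn{M_X(t)}; exactly 1 at `t = 0`.
#' @export
ofhl_mgf <- function(t, alpha, theta,
                     method = c("auto", "series", "quadrature"),
                     control = ofhl_series_control(), max_terms = 200L) {
  method <- match.arg(method)
  .ofhl_check_params(alpha, theta)
  if (!is.numeric(t) || length(t) != 1L || is.na(t))
    stop("'t' must be a single number", call. = FALSE)
  if (t >= theta * min(alpha, 1))
    stop(sprintf("'t' must be below the exponential-tail bound theta*min(alpha,1) = %g",
                 theta * min(alpha, 1)), call. = FALSE)
  if (t == 0) return(1)
  total <- 1; term_prev <- Inf; n_small <- 0; n_grow <- 0
  for (r in seq_len(max_terms)) {
    m_r <- ofhl_moment(r, alpha, theta, method = method, control = control)
    term <- t^r * m_r / factorial(r)
    total <- total + term
    if (abs(term) < control$rel_tol * abs(total)) {
      n_small <- n_small + 1
      if (n_small >= 3) return(total)
    } else n_small <- 0
    if (r > 10 && abs(term) > abs(term_prev)) {
      n_grow <- n_grow + 1
      if (n_grow >= 5)
        stop(errorCondition("MGF Maclaurin series is diverging",
                            class = c("ofhl_nonconvergence", "error", "condition"),
                            partial = total))
    } else n_grow <- 0
    term_prev <- term
  }
  stop(errorCondition("MGF Maclaurin series did not converge within 'max_terms'",
                      class = c("ofhl_nonconvergence", "error", "condition"),
                      partial = total))
}

#' Incomplete moments of the OFHL distribution
#'
#' The lower incomplete moment
#' \eqn{\varphi_r(y) = \int_0^y x^r f(x)\,dx}, via the series expansion with
#' the lower incomplete gamma function
#' \eqn{\gamma\{r+1, (\alpha(k+1)+\ell)\theta y\}} replacing
#' \eqn{\Gamma(r+1)}, or by quadrature. Non-decreasing in `y`, tending to
#' [ofhl_moment()] as `y` grows.
#'
#' @param y positive truncation point.
#' @inheritParams ofhl_moment
#' @return \eqn{\varphi_r(y)}, a non-negative number.
#' @export
ofhl_inc_moment <- function(r, y, alpha, theta,
                            method = c("auto", "series", "quadrature"),
                            control = ofhl_series_control()) {
  method <- match.arg(method)
  .ofhl_check_params(alpha, theta)
  r <- .ofhl_check_r(r)
  if (!is.numeric(y) || length(y) != 1L || is.na(y) || y <= 0)
    stop("'y' must be a single positive number", call. = FALSE)
  # for y deep in the upper tail integrate the (negligible) tail instead, so
  # the quadrature never hunts for a mass spike inside an enormous interval
  quad <- function() {
    if (pofhl(y, alpha, theta) > 0.5) {
      .ofhl_quad_moment(r, alpha, theta) -
        integrate(function(x) x^r * dofhl(x, alpha, theta), y, Inf,
                  rel.tol = 1e-10, subdivisions = 400L)$value
    } else {
      integrate(function(x) x^r * dofhl(x, alpha, theta), 0, y,
                rel.tol = 1e-10, subdivisions = 400L)$value
    }
  }
  if (method == "quadrature") return(quad())
  series <- function()
    alpha * gamma(r + 1) / theta^r *
      .ofhl_series_sum(alpha,
                       function(c) c^(-(r + 1)) * pgamma(c * theta * y, r + 1),
                       control, sprintf("phi_%d(%g)", r, y))
  if (method == "series") return(series())
  tryCatch(series(), ofhl_nonconvergence = function(e) quad())
}

#' Conditional moments of the OFHL distribution
#'
#' \eqn{\Delta_r(y) = E[X^r \mid X > y]
#'   = (E[X^r] - \varphi_r(y)) / R(y)}, with the survival function
#' \eqn{R(y)} in the denominator.
#'
#' @inheritParams ofhl_inc_moment
#' @return \eqn{\Delta_r(y)}, a non-negative number.
#' @export
ofhl_cond_moment <- function(r, y, alpha, theta,
                             method = c("auto", "series", "quadrature"),
                             control = ofhl_series_control()) {
  method <- match.arg(method)
  .ofhl_check_params(alpha, theta)
  s <- pofhl(y, alpha, theta, lower.tail = FALSE)
  if (s <= 0)
    stop("survival function is 0 at 'y'; the conditional moment is undefined",
         call. = FALSE)
  (ofhl_moment(r, alpha, theta, method, control) -
     ofhl_inc_moment(r, y, alpha, theta, method, control)) / s
}

#' Mean residual life of the OFHL distribution
#'
#' Expected remaining lifetime of an item that has survived to age `t`:
#' \eqn{\pi(t) = [E(X) - \varphi_1(t)]/R(t) - t}, which also equals
#' \eqn{\Delta_1(t) - t}. Tends to the mean as \eqn{t \to 0^+}.
#'
#' @param t positive age with `pofhl(t, ..., lower.tail = FALSE) > 0`.
#' @inheritParams ofhl_moment
#' @return \eqn{\pi(t) \ge 0}.
#' @export
ofhl_mrl <- function(t, alpha, theta,
                     method = c("auto", "series", "quadrature"),
                     control = ofhl_series_control()) {
  method <- match.arg(method)
  .ofhl_check_params(alpha, theta)
  s <- pofhl(t, alpha, theta, lower.tail = FALSE)
  if (s <= 0)
    stop("survival function is 0 at 't'; mean residual life is undefined",
         call. = FALSE)
  if (s < 1e-30) {
    # the tail-mass ratio is hopeless in double precision; integrate the
    # survival ratio S(x)/S(t) in log space instead (pi(t) = int_t^Inf S/S(t))
    log_S <- function(x) {
      ga <- exp(alpha * .ofhl_log_g(x, theta))
      out <- numeric(length(ga))
      tiny <- ga < 1e-8
      out[tiny] <- base::log(ga[tiny]) + log1p(-ga[tiny] / 2)
      out[!tiny] <- base::log(-expm1(-ga[!tiny]))
      out
    }
    lst <- log_S(t)
    return(integrate(function(x) exp(log_S(x) - lst), t, Inf,
                     rel.tol = 1e-10, subdivisions = 400L)$value)
  }
  (ofhl_moment(1, alpha, theta, method, control) -
     ofhl_inc_moment(1, t, alpha, theta, method, control)) / s - t
}

#' Mean waiting time of the OFHL distribution
#'
#' Expected elapsed time since failure for an item known to have failed in
#' \eqn{[0, t]}: \eqn{\bar\pi(t) = t - \varphi_1(t)/F(t)}; lies in
#' \eqn{[0, t]}.
#'
#' @param t positive time with `pofhl(t, ...) > 0`.
#' @inheritParams ofhl_moment
#' @return \eqn{\bar\pi(t) \in [0, t]}.
#' @export
ofhl_mwt <- function(t, alpha, theta,
                     method = c("auto", "series", "quadrature"),
                     control = ofhl_series_control()) {
  method <- match.arg(method)
  .ofhl_check_params(alpha, theta)
  F <- pofhl(t, alpha, theta)
  if (F <= 0)
    stop("distribution function is 0 at 't'; mean waiting time is undefined",
         call. = FALSE)
  if (F < 1e-30) {
    # phi_1(t)/F(t) cannot be formed reliably once F underflows this far;
    # by parts, pi-bar(t) = int_0^t F(x)/F(t) dx with the ratio in log space
    # (log F = -g^alpha), which keeps the integrand in [0, 1]
    ga_t <- exp(alpha * .ofhl_log_g(t, theta))
    return(integrate(function(x)
      exp(ga_t - exp(alpha * .ofhl_log_g(x, theta))), 0, t,
      rel.tol = 1e-10, subdivisions = 400L)$value)
  }
  t - ofhl_inc_moment(1, t, alpha, theta, method, control) / F
}
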