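# Distribution functions of the odd Frechet half-logistic (OFHL) model.
#
# Everything runs through the log odds ratio
#   log g(x) = log 2 - theta*x - log1p(-exp(-theta*x)),
# which is stable both for small x (where g blows up) and large x (where g
# underflows): g^alpha is only ever formed as exp(alpha * log g).

.ofhl_check_params <- function(alpha, theta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a single positive finite number", call. = FALSE)
  invisible(TRUE)
}

# log g(x) for x > 0 (vectorised)
.ofhl_log_g <- function(x, theta) log(2) - theta * x - log1p(-exp(-theta * x))

#' The odd Frechet half-logistic distribution
#'
#' Density, distribution function, quantile function, random generation,
#' survival and hazard for the OFHL distribution with shape parameters
#' `alpha` and `theta`.
#'
#' The CDF is \eqn{F(x) = \exp\{-g(x)^\alpha\}} with odds ratio
#' \eqn{g(x) = 2 e^{-\theta x} / (1 - e^{-\theta x})}, and the density is
#' \deqn{f(x) = \frac{\alpha\theta (2 e^{-\theta x})^\alpha}
#'   {(1 - e^{-\theta x})^{\alpha + 1}} \exp\{-g(x)^\alpha\}.}
#' The quantile function is closed form:
#' \eqn{Q(u) = \theta^{-1} \log[1 + 2 (-\log u)^{-1/\alpha}]}, so random
#' generation is by inverse transform.
#'
#' By convention `dofhl` returns 0 and `pofhl` returns the limit values for
#' `x <= 0`; both parameters must be strictly positive.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations.
#' @param alpha,theta positive shape parameters.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)} (the reliability function).
#' @param seed optional integer; if supplied, the draw is made under this
#'   seed and the caller's RNG state is restored afterwards.
#'
#' @return `dofhl` the density, `pofhl` the distribution (or survival)
#'   function, `qofhl` the quantile function, `rofhl` random deviates,
#'   `hofhl` the hazard rate.
#'
#' @examples
#' pofhl(log(3), 1, 1)        # exp(-1): g(log 3) = 1
#' qofhl(0.5, 1, 1)           # the median, log(1 + 2/log 2)
#' x <- rofhl(500, 1.5, 0.5)
#' @name ofhl-distribution
NULL

#' @rdname ofhl-distribution
#' @export
dofhl <- function(x, alpha, theta, log = FALSE) {
  .ofhl_check_params(alpha, theta)
  ld <- rep(-Inf, length(x))
  pos <- is.finite(x) & x > 0
  if (any(pos)) {
    xp <- x[pos]
    lg <- .ofhl_log_g(xp, theta)
    ld[pos] <- base::log(alpha) + base::log(theta) + alpha * lg -
      log1p(-exp(-theta * xp)) - exp(alpha * lg)
  }
  ld[is.na(x)] <- NA_real_
  if (log) ld else exp(ld)
}

#' @rdname ofhl-distribution
#' @export
pofhl <- function(q, alpha, theta, lower.tail = TRUE, log.p = FALSE) {
  .ofhl_check_params(alpha, theta)
  ga <- rep(Inf, length(q))  # g^alpha -> Inf as x -> 0+, so F -> 0
  pos <- is.finite(q) & q > 0
  ga[pos] <- exp(alpha * .ofhl_log_g(q[pos], theta))
  p <- if (lower.tail) exp(-ga) else -expm1(-ga)
  p[is.na(q)] <- NA_real_
  if (log.p) base::log(p) else p
}

#' @rdname ofhl-distribution
#' @export
qofhl <- function(p, alpha, theta) {
  .ofhl_check_params(alpha, theta)
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  log1p(2 * (-base::log(p))^(-1 / alpha)) / theta
}

#' @rdname ofhl-distribution
#' @export
rofhl <- function(n, alpha, theta, seed = NULL) {
  .ofhl_check_params(alpha, theta)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  qofhl(runif(n), alpha, theta)
}

#' @rdname ofhl-distribution
#' @export
hofhl <- function(x, alpha, theta) {
  f <- dofhl(x, alpha, theta)
  s <- pofhl(x, alpha, theta, lower.tail = FALSE)
  h <- ifelse(s > 0, f / s, Inf)
  if (any(s == 0 & !is.na(s)))
    warning("survival function underflowed to 0; hazard reported as Inf")
  h
}

#' Median of the OFHL distribution
#'
#' Closed form: `qofhl(0.5, alpha, theta)`; `theta` enters only as the `1/theta`
#' prefactor, so doubling `theta` halves the median.
#'
#' @inheritParams ofhl-distribution
#' @return The median, a positive number.
#' @export
ofhl_median <- function(alpha, theta) qofhl(0.5, alpha, theta)

#' Extreme order statistics of an OFHL sample
#'
#' Density and CDF of the sample maximum (\eqn{F_{n:n} = F^n}) or minimum
#' (\eqn{F_{1:n} = 1 - (1-F)^n}) of `n` i.i.d. OFHL observations.
#'
#' @inheritParams ofhl-distribution
#' @param n sample size the extreme is taken over (`n >= 1`).
#' @param extreme `"maximum"` or `"minimum"`.
#' @return A `data.frame` with columns `x`, `pdf` and `cdf`.
#' @examples
#' ofhl_order_stat(ofhl_median(1, 1), 1, 1, n = 3)$cdf  # (1/2)^3
#' @export
ofhl_order_stat <- function(x, alpha, theta, n, extreme = c("maximum", "minimum")) {
  extreme <- match.arg(extreme)
  .ofhl_check_params(alpha, theta)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  f <- dofhl(x, alpha, theta)
  if (extreme == "maximum") {
    F <- pofhl(x, alpha, theta)
    data.frame(x = x, pdf = n * F^(n - 1) * f, cdf = F^n)
  } else {
    S <- pofhl(x, alpha, theta, lower.tail = FALSE)
    data.frame(x = x, pdf = n * S^(n - 1) * f, cdf = 1 - S^n)
  }
}

#' Half-logistic baseline distribution
#'
#' Density and CDF of the one-parameter half-logistic model
#' \eqn{M(x;\theta) = (1 - e^{-\theta x})/(1 + e^{-\theta x})}, the baseline
#' the OFHL model extends and the comparison model in the goodness-of-fit
#' reports.
#'
#' @param x,q vector of quantiles.
#' @param theta positive shape parameter.
#' @param log,log.p,lower.tail as in [dofhl()]/[pofhl()].
#' @return Density (`dhl`) or distribution function (`phl`) values.
#' @export
dhl <- function(x, theta, log = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a single positive finite number", call. = FALSE)
  ld <- rep(-Inf, length(x))
  pos <- is.finite(x) & x > 0
  ld[pos] <- base::log(2 * theta) - theta * x[pos] - 2 * log1p(exp(-theta * x[pos]))
  ld[is.na(x)] <- NA_real_
  if (log) ld else exp(ld)
}

#' @rdname dhl
#' @export
phl <- function(q, theta, lower.tail = TRUE, log.p = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a single positive finite number", call. = FALSE)
  p <- numeric(length(q))
  pos <- is.finite(q) & q > 0
  e <- exp(-theta * q[pos])
  p[pos] <- (1 - e) / (1 + e)
  p[is.na(q)] <- NA_real_
  if (!lower.tail) p <- 1 - p
  if (log.p) base::log(p) else p
}
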