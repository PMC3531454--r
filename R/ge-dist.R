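#' Generalized exponential (GE) waiting-time distribution
#'
#' Constructs a GE distribution with density
#' \deqn{f(t) = a \lambda e^{-\lambda t} (1 - e^{-\lambda t})^{a-1}, \quad t \ge 0,}
#' the workhorse waiting-time density of the hierarchic stochastic model.
#' For integer shape `a` it is the distribution of the maximum of `a`
#' independent exponentials with rate `lambda`; `a = 1` is the exponential
#' distribution itself. Non-integer shapes are permitted (fits produce them).
#'
#' @param shape Shape parameter `a` (dimensionless, > 0).
#' @param rate Scale parameter `lambda` (s^-1, > 0).
#' @return An object of class `ge_dist`.
#' @examples
#' d <- ge_dist(shape = 2, rate = 5)
#' ge_pdf(0.1, d)
#' ge_moment(1, d)  # mean waiting time, s
#' @export
ge_dist <- function(shape, rate) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single finite number > 0 (s^-1)", call. = FALSE)
  structure(list(shape = as.numeric(shape), rate = as.numeric(rate)),
            class = "ge_dist")
}

#' @export
print.ge_dist <- function(x, ...) {
  cat(sprintf("GE waiting-time distribution: shape a = %g, rate lambda = %g s^-1\n",
              x$shape, x$rate))
  cat(sprintf("  mean %.4g s, sd %.4g s\n", ge_moment(1, x),
              sqrt(ge_moment(2, x) - ge_moment(1, x)^2)))
  invisible(x)
}

#' Exponential distribution as a GE special case
#'
#' @param rate Rate in s^-1.
#' @return A `ge_dist` with shape 1.
#' @export
exp_dist <- function(rate) ge_dist(shape = 1, rate = rate)

#' GE probability density
#'
#' Evaluated in the log domain so that survival tails with `rate * t >> 1`
#' do not underflow prematurely; `t < 0` returns 0 by convention.
#'
#' @param t Time(s), s.
#' @param d A [ge_dist()].
#' @param log Return the log density?
#' @return Density values, s^-1.
#' @export
ge_pdf <- function(t, d, log = FALSE) {
  stopifnot(inherits(d, "ge_dist"))
  a <- d$shape; lam <- d$rate
  t <- as.numeric(t)
  lf <- rep(-Inf, length(t))
  ok <- is.finite(t) & t >= 0
  tt <- t[ok]
  # (a-1) * log(1 - exp(-lam t)) ; at t = 0 this is -Inf for a > 1, 0 for a = 1
  l1me <- log1p(-exp(-lam * tt))
  body <- log(a) + log(lam) - lam * tt
  if (a != 1) body <- body + (a - 1) * l1me
  lf[ok] <- body
  lf[!is.finite(t) & !is.na(t)] <- -Inf
  if (log) lf else exp(lf)
}

#' GE survival function
#'
#' `S(t) = 1 - (1 - e^{-lambda t})^a`, computed as
#' `-expm1(a * log1p(-exp(-lambda t)))` for stability at large `lambda * t`.
#'
#' @inheritParams ge_pdf
#' @return Survival probabilities in \[0, 1\].
#' @export
ge_survival <- function(t, d) {
  stopifnot(inherits(d, "ge_dist"))
  a <- d$shape; lam <- d$rate
  t <- as.numeric(t)
  s <- numeric(length(t))
  neg <- !is.na(t) & t < 0
  s[neg] <- 1
  ok <- is.finite(t) & t >= 0
  s[ok] <- -expm1(a * log1p(-exp(-lam * t[ok])))
  s[is.na(t)] <- NA_real_
  s
}

#' GE cumulative distribution function
#'
#' @inheritParams ge_pdf
#' @return `(1 - e^{-lambda t})^a`.
#' @export
ge_cdf <- function(t, d) 1 - ge_survival(t, d)

#' GE quantile function
#'
#' Closed form `t = -log(1 - p^{1/a}) / lambda`.
#'
#' @param p Probabilities in \[0, 1).
#' @param d A [ge_dist()].
#' @return Quantiles, s.
#' @export
ge_quantile <- function(p, d) {
  stopifnot(inherits(d, "ge_dist"))
  if (any(p < 0 | p >= 1, na.rm = TRUE))
    stop("'p' must lie in [0, 1)", call. = FALSE)
  -log1p(-p^(1 / d$shape)) / d$rate
}

#' Sample GE waiting times
#'
#' Inverse-CDF sampling via the closed-form quantile.
#'
#' @param n Number of draws.
#' @param d A [ge_dist()].
#' @return Numeric vector of waiting times, s.
#' @export
rge <- function(n, d) ge_quantile(stats::runif(n), d)

#' Laplace transform of the GE density
#'
#' \deqn{\hat\psi(s) = a\,B(1 + s/\lambda,\ a)}
#' with `B` the Beta function; equals `integral e^{-st} f(t) dt`. Real
#' arguments use `lbeta`; complex arguments (with `Re(s) >= 0`) go through the
#' complex Gamma function.
#'
#' @param s Transform variable(s), real or complex, `Re(s) >= 0` and
#'   `1 + Re(s)/lambda > 0`.
#' @param d A [ge_dist()].
#' @return Transform values (dimensionless).
#' @export
ge_laplace <- function(s, d) {
  stopifnot(inherits(d, "ge_dist"))
  a <- d$shape; lam <- d$rate
  if (any(1 + Re(s) / lam <= 0))
    stop("ge_laplace: require 1 + Re(s)/rate > 0", call. = FALSE)
  if (is.complex(s)) {
    z <- 1 + s / lam
    a * pracma::gammaz(z) * gamma(a) / pracma::gammaz(z + a)
  } else {
    a * exp(lbeta(1 + s / lam, a))
  }
}

#' Raw moments of a GE distribution
#'
#' `m_n = integral t^n f(t) dt`. The mean uses the digamma identity
#' `E[T] = (psi(a + 1) - psi(1)) / lambda`; higher moments use adaptive
#' quadrature on `[0, t*]` with `t*` chosen so the survival is below 1e-12.
#'
#' @param n Moment order, integer >= 0.
#' @param d A [ge_dist()].
#' @return The raw moment, units s^n.
#' @export
ge_moment <- function(n, d) {
  stopifnot(inherits(d, "ge_dist"))
  if (length(n) != 1L || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  if (n == 0) return(1)
  if (n == 1) return((digamma(d$shape + 1) - digamma(1)) / d$rate)
  tstar <- ge_quantile(1 - 1e-12, d) * (n + 1)
  stats::integrate(function(t) t^n * ge_pdf(t, d), 0, tstar,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}
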