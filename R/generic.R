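#' Generic spike model parameters
#'
#' The generic model describes global spikes as an inhomogeneous Poisson
#' process: each cluster `i` produces puffs at rate `lambda_i`, a puff
#' escalates into a global spike with probability `xi_i` (the coupling
#' strength, a splitting probability), and after a spike the intensity
#' recovers from zero at rate `rho` (global negative feedback). The spike
#' intensity is
#' \deqn{\Lambda(t) = \Big(\sum_i \xi_i \lambda_i\Big)\,(1 - e^{-\rho t}),}
#' so the probability of a spike immediately after a spike is zero.
#' `rho = Inf` removes the feedback (constant intensity).
#'
#' @param puff_rates Per-cluster puff rates `lambda_i`, s^-1 (recycled to
#'   `n_clusters` if scalar).
#' @param couplings Per-cluster coupling strengths `xi_i` in \[0, 1\]
#'   (recycled).
#' @param rho Recovery rate, s^-1 (> 0, `Inf` allowed).
#' @param n_clusters Number of clusters (default: length of the longer of
#'   `puff_rates`/`couplings`).
#' @return An object of class `generic_params` with the asymptotic spike
#'   rate `lambda_inf = sum(xi_i lambda_i)`.
#' @export
generic_params <- function(puff_rates, couplings, rho,
                           n_clusters = max(length(puff_rates),
                                            length(couplings))) {
  stopifnot(n_clusters >= 1)
  puff_rates <- rep_len(as.numeric(puff_rates), n_clusters)
  couplings <- rep_len(as.numeric(couplings), n_clusters)
  if (any(puff_rates <= 0) || any(!is.finite(puff_rates)))
    stop("'puff_rates' must be finite and > 0", call. = FALSE)
  if (any(couplings < 0 | couplings > 1))
    stop("'couplings' must lie in [0, 1]", call. = FALSE)
  if (!(is.numeric(rho) && length(rho) == 1L && rho > 0))
    stop("'rho' must be a single rate > 0 (Inf allowed)", call. = FALSE)
  lam_inf <- sum(couplings * puff_rates)
  if (lam_inf <= 0) stop("total spike rate is zero", call. = FALSE)
  structure(list(puff_rates = puff_rates, couplings = couplings, rho = rho,
                 n_clusters = n_clusters, lambda_inf = lam_inf),
            class = "generic_params")
}

#' @export
print.generic_params <- function(x, ...) {
  cat(sprintf(paste0("Generic spike model: %d clusters, total spike rate ",
                     "lambda_inf = %g s^-1, recovery rho = %g s^-1\n"),
              x$n_clusters, x$lambda_inf, x$rho))
  invisible(x)
}

#' Time-dependent spike intensity
#'
#' `Lambda(t) = lambda_inf (1 - e^{-rho t})`; zero at `t = 0` for finite
#' `rho`, constant `lambda_inf` when `rho = Inf`.
#'
#' @param t Time(s) since the last spike, s.
#' @param p A [generic_params()].
#' @return Intensity, s^-1.
#' @export
spike_intensity <- function(t, p) {
  stopifnot(inherits(p, "generic_params"))
  if (is.infinite(p$rho)) return(rep(p$lambda_inf, length(t)))
  p$lambda_inf * (-expm1(-p$rho * t))
}

# cumulative hazard: integral_0^t Lambda = lambda_inf (t - (1 - e^{-rho t})/rho)
generic_cum_hazard <- function(t, p) {
  if (is.infinite(p$rho)) return(p$lambda_inf * t)
  p$lambda_inf * (t - (-expm1(-p$rho * t)) / p$rho)
}

#' Interspike-interval density of the generic model
#'
#' `p(t) = Lambda(t) exp(-integral_0^t Lambda)`, the waiting-time density of
#' the inhomogeneous Poisson spike process after a renewal (spike) at
#' `t = 0`; the cumulative hazard is available in closed form.
#'
#' @inheritParams spike_intensity
#' @return Density values, s^-1.
#' @export
isi_density_generic <- function(t, p) {
  spike_intensity(t, p) * exp(-generic_cum_hazard(t, p))
}

#' ISI survival function of the generic model
#'
#' @inheritParams spike_intensity
#' @return `exp(-integral_0^t Lambda)`.
#' @export
isi_survival_generic <- function(t, p) exp(-generic_cum_hazard(t, p))

#' Analytical ISI moments of the generic model
#'
#' Raw moments by adaptive quadrature in the survival form
#' `<T^n> = n integral t^{n-1} S(t) dt` (exact closed forms when
#' `rho = Inf`, where the ISI is exponential).
#'
#' @param p A [generic_params()].
#' @param n_max Highest moment, <= 4.
#' @return An `fpt_summary`.
#' @export
generic_moments <- function(p, n_max = 4) {
  stopifnot(inherits(p, "generic_params"), n_max >= 1, n_max <= 4)
  if (is.infinite(p$rho)) {
    m <- factorial(1:4) / p$lambda_inf^(1:4)
  } else {
    # cut-off where the cumulative hazard reaches ~40 (S < 1e-17)
    thi <- 40 / p$lambda_inf + 1 / p$rho
    while (generic_cum_hazard(thi, p) < 40) thi <- thi * 2
    m <- vapply(1:4, function(n)
      tryCatch(
        n * stats::integrate(function(t) t^(n - 1) * isi_survival_generic(t, p),
                             0, thi, rel.tol = 1e-10,
                             subdivisions = 500L)$value,
        error = function(e)
          stop(sprintf("moment quadrature failed (n = %d, lambda_inf = %g, rho = %g): %s",
                       n, p$lambda_inf, p$rho, conditionMessage(e)),
               call. = FALSE)),
      numeric(1))
  }
  out <- fpt_summary_from_moments(m)
  if (n_max < 4) out$moments <- out$moments[1:n_max]
  out
}

#' Coupling strength from the mechanistic chain
#'
#' The generic model's coupling strength is the splitting probability of the
#' mechanistic cluster chain: the probability that a single open cluster
#' escalates to the spike state before the system returns to all-closed.
#'
#' @param x An [sm_chain()] (typically from [spike_chain()]) or `sm_cwt`.
#' @param target Spike state; default the chain's `target_state` (or the
#'   highest state).
#' @return Coupling strength `xi` in (0, 1\].
#' @export
coupling_from_mechanistic <- function(x, target = NULL) {
  cwt <- as_cwt(x)
  K <- cwt$n_states
  tg <- if (!is.null(target)) resolve_state(cwt, target)
        else cwt$chain$target_state %||% K
  if (tg == 2L) return(1)  # spike defined as the first opening itself
  splitting_probability(cwt, from = 2L, up = tg, down = 1L)
}

#' Sample an ISI sequence from the generic model
#'
#' Draws interspike intervals by numerical inversion of the closed-form
#' cumulative hazard (bisection via `uniroot` to 1e-10); the process renews
#' after each spike, with the intensity recovering from zero.
#'
#' @param p A [generic_params()].
#' @param n_spikes Number of spikes to draw (>= 1).
#' @param seed Optional seed.
#' @return A `spike_train`.
#' @export
sample_generic_train <- function(p, n_spikes, seed = NULL) {
  stopifnot(inherits(p, "generic_params"), n_spikes >= 1)
  if (!is.null(seed)) set.seed(seed)
  e <- stats::rexp(n_spikes)
  if (is.infinite(p$rho)) {
    isis <- e / p$lambda_inf
  } else {
    isis <- vapply(e, function(h) {
      lo <- 0; hi <- h / p$lambda_inf + 1 / p$rho
      while (generic_cum_hazard(hi, p) < h) hi <- hi * 2
      stats::uniroot(function(t) generic_cum_hazard(t, p) - h,
                     c(lo, hi), tol = 1e-10)$root
    }, numeric(1))
  }
  epochs <- cumsum(isis)
  structure(list(spike_epochs = epochs, isis = isis[-1],
                 target_state = "spike", reset_state = "spike",
                 t_max = epochs[length(epochs)]),
            class = "spike_train")
}

#' Sigma vs T_av moment relation of the generic model
#'
#' Sweeps the asymptotic spike rate `lambda_inf` at fixed recovery `rho`,
#' computes (T_av, sigma) per point and fits the linear moment relation by
#' ordinary least squares. Changing the coupling strength `xi` only rescales
#' `lambda_inf`, so it moves a cell along the same relation without
#' changing its slope.
#'
#' @param lambda_inf Sweep of asymptotic spike rates, s^-1 (>= 5 values).
#' @param rho Recovery rate, s^-1 (Inf allowed).
#' @return Object of class `moment_relation`: data.frame `points`
#'   (columns `lambda_inf_per_s`, `t_av_s`, `sigma_s`), `slope`,
#'   `intercept_s`.
#' @export
moment_relation <- function(lambda_inf, rho) {
  if (length(lambda_inf) < 5)
    stop("need at least 5 sweep points", call. = FALSE)
  pts <- do.call(rbind, lapply(lambda_inf, function(l) {
    s <- generic_moments(generic_params(l, 1, rho, 1), n_max = 2)
    data.frame(lambda_inf_per_s = l, t_av_s = s$mean, sigma_s = s$sd)
  }))
  fit <- stats::lm(sigma_s ~ t_av_s, data = pts)
  structure(list(points = pts,
                 slope = unname(stats::coef(fit)[2]),
                 intercept_s = unname(stats::coef(fit)[1]),
                 rho = rho),
            class = "moment_relation")
}

#' @export
print.moment_relation <- function(x, ...) {
  cat(sprintf("sigma-T_av moment relation (rho = %g s^-1): slope %.6f, intercept %.4g s over %d points\n",
              x$rho, x$slope, x$intercept_s, nrow(x$points)))
  invisible(x)
}

#' Approximation error of the generic model versus the exact chain
#'
#' Compares, without recovery (`rho = Inf`), the generic-model mean ISI
#' `1/(lambda_puff xi)` with the exact first-passage mean of the mechanistic
#' chain, per sweep point. The Poisson-splitting construction neglects the
#' duration of failed puff excursions, whose expected number per spike is
#' `(1 - xi)/xi`, so the relative error grows about linearly in that
#' quantity and stays small under time-scale separation.
#'
#' @param chains List of [spike_chain()] models (e.g. one per stimulation
#'   level), each with an exponential ground-state transition.
#' @return data.frame with one row per chain: `lambda_puff_per_s`, `xi`,
#'   `failed_puffs` (`(1 - xi)/xi`), `t_av_exact_s`, `t_av_generic_s`,
#'   `abs_error_s` (the neglected excursion time per spike, which grows
#'   linearly with `failed_puffs`) and `rel_error`.
#' @export
approximation_error <- function(chains) {
  if (inherits(chains, "sm_chain")) chains <- list(chains)
  out <- lapply(chains, function(ch) {
    stopifnot(inherits(ch, "sm_chain"))
    cand0 <- ch$trans[[1]]
    if (length(cand0) != 1L || cand0[[1]]$dist$shape != 1)
      stop("ground state must have a single exponential (puff) transition",
           call. = FALSE)
    lam <- cand0[[1]]$mult * cand0[[1]]$dist$rate
    tg <- ch$target_state %||% ch$n_states
    cwt <- build_conditioned_waiting_times(ch)
    xi <- coupling_from_mechanistic(cwt, target = tg)
    exact <- fpt_moments(cwt, 1L, tg, n_max = 2)$mean
    approx <- 1 / (lam * xi)
    data.frame(lambda_puff_per_s = lam, xi = xi,
               failed_puffs = (1 - xi) / xi,
               t_av_exact_s = exact, t_av_generic_s = approx,
               abs_error_s = abs(exact - approx),
               rel_error = abs(exact - approx) / exact)
  })
  do.call(rbind, out)
}
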