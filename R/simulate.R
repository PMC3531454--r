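#' Simulate a semi-Markov trajectory
#'
#' Delayed Gillespie-type simulation: at each state entry one candidate
#' sojourn is drawn per allowed transition from its basic waiting-time
#' density (for a candidate with multiplicity `m`, the minimum of `m`
#' independent draws, sampled in one step through the survival power
#' `S^m`), and the smallest draw wins. This competing-risks sampling is
#' exactly consistent with the `Psi_ij` product construction. All cluster
#' clocks restart on every state change (semi-Markov renewal assumption).
#'
#' @param chain An [sm_chain()].
#' @param t_max Simulation horizon, s.
#' @param seed Optional integer seed (trajectories are reproducible).
#' @param start Initial state (name or index), default state 1.
#' @return Object of class `sm_trajectory`: data.frame `events` with columns
#'   `time_s` (event times, strictly increasing) and `state` (observable
#'   state label after the event), plus `start`, `t_max`, `seed`.
#' @export
simulate_trajectory <- function(chain, t_max, seed = NULL, start = 1L) {
  stopifnot(inherits(chain, "sm_chain"), t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  i <- resolve_state(chain, start)
  t <- 0
  # grow-and-trim event buffers
  cap <- 1024L
  times <- numeric(cap); states <- integer(cap)
  n <- 0L
  repeat {
    cands <- chain$trans[[i]]
    if (length(cands) == 0) break  # absorbing
    best_t <- Inf; best_j <- NA_integer_
    for (cd in cands) {
      u <- stats::runif(1)
      # minimum of mult iid draws: survival S^mult, quantile at 1 - u^{1/mult}
      tau <- ge_quantile(1 - u^(1 / cd$mult), cd$dist)
      if (tau < best_t) { best_t <- tau; best_j <- cd$to }
    }
    t <- t + best_t
    if (t > t_max) break
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(times) <- cap; length(states) <- cap
    }
    times[n] <- t; states[n] <- best_j
    i <- best_j
  }
  structure(list(events = data.frame(time_s = times[seq_len(n)],
                                     state = chain$state_names[states[seq_len(n)]]),
                 start = chain$state_names[resolve_state(chain, start)],
                 state_names = chain$state_names,
                 t_max = t_max, seed = seed),
            class = "sm_trajectory")
}

#' @export
print.sm_trajectory <- function(x, ...) {
  cat(sprintf("Semi-Markov trajectory: %d events over %g s (start '%s')\n",
              nrow(x$events), x$t_max, x$start))
  invisible(x)
}

#' Fraction of time spent in each state
#'
#' Ergodic occupancy average of a trajectory, comparable to
#' [stationary_occupancy()].
#'
#' @param traj An [simulate_trajectory()] result.
#' @return Named vector of time fractions.
#' @export
occupancy_fraction <- function(traj) {
  stopifnot(inherits(traj, "sm_trajectory"))
  tt <- c(0, traj$events$time_s, traj$t_max)
  st <- c(traj$start, traj$events$state)
  dur <- diff(tt)
  out <- tapply(dur, factor(st, levels = traj$state_names), sum)
  out[is.na(out)] <- 0
  out / traj$t_max
}

#' Extract the spike train from a trajectory
#'
#' A spike epoch is the first entry into `target_state` since the last
#' renewal; after a spike the interspike-interval clock restarts at the next
#' entry into `reset_state` (renewal convention, matching the definition of
#' the ISI as the first-passage time from the reset state to the target).
#'
#' @param traj An `sm_trajectory`.
#' @param target_state Spike state (name or index).
#' @param reset_state Renewal state, default `"0"`/state 1.
#' @return Object of class `spike_train`: `spike_epochs` (s) and `isis`
#'   (s, one per completed renewal cycle).
#' @export
extract_spikes <- function(traj, target_state, reset_state = 1L) {
  stopifnot(inherits(traj, "sm_trajectory"))
  tg <- traj$state_names[resolve_state(traj, target_state)]
  rs <- traj$state_names[resolve_state(traj, reset_state)]
  ev <- traj$events
  epochs <- numeric(0)
  isis <- numeric(0)
  armed <- identical(traj$start, rs)
  clock <- 0
  for (k in seq_len(nrow(ev))) {
    s <- ev$state[k]; tk <- ev$time_s[k]
    if (!armed && s == rs) { armed <- TRUE; clock <- tk }
    else if (armed && s == tg) {
      epochs <- c(epochs, tk)
      if (length(epochs) > 1L) isis <- c(isis, tk - clock)
      armed <- FALSE
    }
  }
  structure(list(spike_epochs = epochs, isis = isis,
                 target_state = tg, reset_state = rs, t_max = traj$t_max),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes (%d complete ISIs) over %g s\n",
              length(x$spike_epochs), length(x$isis), x$t_max))
  invisible(x)
}

#' Sample statistics of an interspike-interval sequence
#'
#' Unbiased mean and standard deviation, standardized third and fourth
#' sample moments, and seeded bootstrap standard errors.
#'
#' @param train A `spike_train`, or a numeric vector of ISIs (s).
#' @param n_boot Bootstrap resamples for standard errors (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An `fpt_summary` with an additional `se` vector (bootstrap
#'   standard errors for mean, sd, cv, skewness, excess kurtosis) and `n`.
#' @export
isi_statistics <- function(train, n_boot = 1000L, seed = NULL) {
  isis <- if (inherits(train, "spike_train")) train$isis else as.numeric(train)
  n <- length(isis)
  if (n < 2) stop("need at least 2 ISIs", call. = FALSE)
  if (n < 100)
    warning("fewer than 100 ISIs: higher sample moments are unreliable")
  stat <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    z <- (x - m) / s
    c(mean = m, sd = s, cv = s / m,
      skewness = mean(z^3),
      excess_kurtosis = mean(z^4) - 3)
  }
  est <- stat(isis)
  if (!is.null(seed)) set.seed(seed)
  bs <- replicate(n_boot, stat(isis[sample.int(n, n, replace = TRUE)]))
  se <- apply(bs, 1, stats::sd)
  raw <- vapply(1:4, function(k) mean(isis^k), numeric(1))
  out <- structure(list(moments = stats::setNames(raw, paste0("m", 1:4)),
                        mean = unname(est["mean"]), sd = unname(est["sd"]),
                        cv = unname(est["cv"]),
                        skewness = unname(est["skewness"]),
                        excess_kurtosis = unname(est["excess_kurtosis"]),
                        se = se, n = n),
                   class = "fpt_summary")
  out
}
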