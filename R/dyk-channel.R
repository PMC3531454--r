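#' De Young-Keizer rate constants
#'
#' Loads the bundled, versioned key-value file with the rate constants of the
#' De Young-Keizer IP3 receptor subunit scheme: five association rates
#' (uM^-1 s^-1) and dissociation constants (uM), one pair per binding
#' context (IP3 with/without inhibitory Ca bound, inhibitory Ca with/without
#' IP3 bound, activating Ca). Dissociation rates are `b_i = a_i * d_i`.
#'
#' @param version Data file version (currently 1).
#' @return A list with `association`, `dissociation_constant`,
#'   `subunits_per_channel`, `open_subunit_threshold`.
#' @export
dyk_rates <- function(version = 1) {
  path <- system.file("extdata", sprintf("dyk_rates_v%d.json", version),
                      package = "caspike")
  if (path == "")
    stop("DYK rate-constant data file not found", call. = FALSE)
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(unlist(r$association) > 0),
            all(unlist(r$dissociation_constant) > 0))
  # detailed balance of the IP3 x inhibitory-Ca cycle
  d <- r$dissociation_constant
  if (abs(d$d1 * d$d2 - d$d3 * d$d4) / (d$d1 * d$d2) > 0.01)
    stop("DYK rates violate detailed balance d1*d2 = d3*d4", call. = FALSE)
  r
}

# 8 subunit states as bits: p = IP3 bound, act = activating Ca bound,
# inh = inhibitory Ca bound. The active state is (1, 1, 0).
dyk_subunit_states <- function() {
  g <- expand.grid(p = 0:1, act = 0:1, inh = 0:1)
  as.matrix(g)
}

# subunit transition-rate matrix at fixed Ca (uM) and IP3 (uM)
dyk_subunit_Q <- function(ca, ip3, rates = dyk_rates()) {
  a <- rates$association; d <- rates$dissociation_constant
  st <- dyk_subunit_states()
  ns <- nrow(st)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    p <- st[i, "p"]; act <- st[i, "act"]; inh <- st[i, "inh"]
    to <- function(p2, a2, h2) which(st[, "p"] == p2 & st[, "act"] == a2 &
                                     st[, "inh"] == h2)
    if (p == 0) Q[i, to(1, act, inh)] <- if (inh == 0) a$a1 * ip3 else a$a3 * ip3
    else        Q[i, to(0, act, inh)] <- if (inh == 0) a$a1 * d$d1 else a$a3 * d$d3
    if (inh == 0) Q[i, to(p, act, 1)] <- if (p == 1) a$a2 * ca else a$a4 * ca
    else          Q[i, to(p, act, 0)] <- if (p == 1) a$a2 * d$d2 else a$a4 * d$d4
    if (act == 0) Q[i, to(p, 1, inh)] <- a$a5 * ca
    else          Q[i, to(p, 0, inh)] <- a$a5 * d$d5
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# all compositions of n into k non-negative parts (rows)
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

#' Build the lumped De Young-Keizer channel generator
#'
#' Constructs the continuous-time Markov chain of one IP3 receptor channel
#' (four identical subunits in the 8-state scheme) at fixed local Ca2+ and
#' IP3, lumped by subunit-count symmetry: a state records how many subunits
#' occupy each of the 8 subunit states (330 lumped states). The channel is
#' open when at least `open_subunit_threshold` (3) subunits are in the active
#' state (IP3 and activating Ca bound, no inhibitory Ca). A cluster consists
#' of `n_ch` independent channels experiencing the same local Ca2+; the
#' cluster's observable open state is ">= 1 channel open".
#'
#' @param params A [cell_params()].
#' @param ca Local Ca2+ level, uM; defaults to `params$ca_base` (the level
#'   relevant for the first, puff-triggering opening).
#' @param rates Rate constants from [dyk_rates()].
#' @return An object of class `dyk_generator`: the lumped state table,
#'   generator matrix `Q` (s^-1), logical `open` mask, and the cell
#'   parameters.
#' @export
build_dyk_generator <- function(params, ca = NULL, rates = dyk_rates()) {
  stopifnot(inherits(params, "cell_params"))
  if (is.null(ca)) ca <- params$ca_base
  qsub <- dyk_subunit_Q(ca, params$ip3, rates)
  nsub <- rates$subunits_per_channel
  st <- compositions(nsub, nrow(qsub))
  sub <- dyk_subunit_states()
  active <- which(sub[, "p"] == 1 & sub[, "act"] == 1 & sub[, "inh"] == 0)
  # base-(nsub+1) encoding for state lookup
  base_pow <- (nsub + 1)^(0:(ncol(st) - 1))
  ids <- as.vector(st %*% base_pow)
  K <- nrow(st)
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    v <- st[i, ]
    for (s in which(v > 0)) {
      for (s2 in which(qsub[s, ] > 0)) {
        if (s2 == s) next
        w <- v; w[s] <- w[s] - 1L; w[s2] <- w[s2] + 1L
        j <- match(sum(w * base_pow), ids)
        Q[i, j] <- Q[i, j] + v[s] * qsub[s, s2]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  open <- st[, active] >= rates$open_subunit_threshold
  structure(list(params = params, ca = ca, rates = rates, states = st,
                 active_state = active, Q = Q, open = open),
            class = "dyk_generator")
}

#' @export
print.dyk_generator <- function(x, ...) {
  cat(sprintf(paste0("De Young-Keizer lumped channel chain: %d states ",
                     "(%d open) at Ca = %g uM, [IP3] = %g uM\n"),
              nrow(x$Q), sum(x$open), x$ca, x$params$ip3))
  invisible(x)
}

#' Stationary distribution of the lumped channel chain
#'
#' @param gen A [build_dyk_generator()] object.
#' @return Named list: `pi` (stationary probabilities over lumped states) and
#'   `p_open` (stationary channel open probability).
#' @export
dyk_stationary <- function(gen) {
  stopifnot(inherits(gen, "dyk_generator"))
  K <- nrow(gen$Q)
  A <- t(gen$Q)
  A[K, ] <- 1
  b <- c(rep(0, K - 1), 1)
  p <- solve(A, b)
  p[p < 0 & p > -1e-12] <- 0
  list(pi = p, p_open = sum(p[gen$open]))
}

#' First-opening-time distribution of a channel
#'
#' The waiting time until a channel first enters the open set, starting from
#' the stationary distribution conditioned on the closed set (interpuff
#' semantics: the channel has been closed for a long time). This is a
#' phase-type distribution with sub-generator `Q_CC`; its survival function
#' is evaluated through the spectral decomposition
#' `S(t) = alpha' exp(Q_CC t) 1`.
#'
#' @param gen A [build_dyk_generator()] object.
#' @param init `"stationary"` (conditioned on closed, the default) or a
#'   probability vector over the closed states.
#' @return Object of class `dyk_fpt`: `survival(t)`, `quantile(p)` (numeric
#'   inversion on a dense grid), `mean` (from the `(-Q_CC)^{-1}` linear
#'   solve), and the conditioning data.
#' @export
dyk_first_opening <- function(gen, init = "stationary") {
  stopifnot(inherits(gen, "dyk_generator"))
  closed <- which(!gen$open)
  Qcc <- gen$Q[closed, closed]
  if (identical(init, "stationary")) {
    p <- dyk_stationary(gen)$pi[closed]
  } else {
    stopifnot(length(init) == length(closed), all(init >= 0))
    p <- init
  }
  alpha <- p / sum(p)
  ones <- rep(1, length(closed))
  mean_t <- as.numeric(alpha %*% solve(-Qcc, ones))
  eg <- eigen(Qcc)
  w <- as.vector(alpha %*% eg$vectors) * as.vector(solve(eg$vectors, ones))
  mu <- eg$values
  surv <- function(t) {
    s <- Re(exp(outer(t, mu)) %*% w)
    pmin(pmax(as.vector(s), 0), 1)
  }
  # dense grid for quantile inversion, down to S = 1e-9
  thi <- mean_t
  while (surv(thi) > 1e-9) thi <- thi * 2
  tg <- c(0, exp(seq(log(mean_t * 1e-7), log(thi), length.out = 3000L)))
  sg <- surv(tg)
  keep <- !duplicated(-sg) & sg > 0
  tg <- tg[keep]; sg <- sg[keep]
  qf <- function(p) {
    # p = target survival value; log-linear interpolation in S
    stats::approx(x = log(sg), y = tg, xout = log(p), rule = 2)$y
  }
  structure(list(survival = surv, quantile = qf, mean = mean_t,
                 alpha = alpha, closed = closed, eigenvalues = mu),
            class = "dyk_fpt")
}

#' Mean first-opening time of a cluster
#'
#' A cluster of `n_ch` independent channels opens when the first channel
#' opens, so the cluster survival is `S(t)^n_ch`; the mean is its integral.
#'
#' @param fpt A [dyk_first_opening()] object.
#' @param n_ch Number of channels per cluster.
#' @return Mean time, s.
#' @export
first_opening_mean <- function(fpt, n_ch = 1) {
  stopifnot(inherits(fpt, "dyk_fpt"))
  if (n_ch == 1) return(fpt$mean)
  thi <- fpt$quantile(1e-12^(1 / n_ch))
  stats::integrate(function(t) fpt$survival(t)^n_ch, 0, thi,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}

#' Sample cluster first-opening times from the De Young-Keizer model
#'
#' Draws waiting times until the first of the cluster's `n_ch` channels
#' opens, each channel started from the stationary distribution conditioned
#' on being closed at the prevailing local Ca2+ level. Sampling inverts the
#' phase-type survival function (the minimum of `n_ch` iid channel times has
#' survival `S(t)^n_ch`, so a uniform draw `u` maps to the channel quantile
#' at `u^{1/n_ch}`); reproducible under `seed`.
#'
#' When sampling the successive-opening context (`ca > ca_base`), the
#' channels of the still-closed cluster were equilibrated at the basal Ca2+
#' level before the neighbouring cluster opened, so the initial distribution
#' is the basal-Ca stationary distribution conditioned on the closed set,
#' evolved under the elevated-Ca rates; this is what produces the CICR
#' acceleration of consecutive openings. Set `ca_init = ca` to start from
#' the prevailing-Ca conditioned stationary instead.
#'
#' @param params A [cell_params()].
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @param ca Local Ca2+ level, uM; default `params$ca_base`.
#' @param ca_init Ca2+ level of the pre-opening equilibrium from which the
#'   closed-set initial distribution is taken; default `params$ca_base`.
#' @param level `"cluster"` (default) or `"channel"` (single-channel times).
#' @param fpt Optionally a precomputed [dyk_first_opening()] (avoids
#'   rebuilding the generator in sweeps).
#' @return Numeric vector of waiting times, s.
#' @export
sample_first_opening_times <- function(params, n, seed = NULL, ca = NULL,
                                       ca_init = NULL,
                                       level = c("cluster", "channel"),
                                       fpt = NULL) {
  stopifnot(n >= 1)
  level <- match.arg(level)
  if (is.null(fpt)) {
    fpt <- dyk_opening_fpt(params, ca = ca, ca_init = ca_init)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  if (level == "cluster") u <- u^(1 / params$n_ch)
  fpt$quantile(u)
}

#' First-opening distribution at a given Ca2+ context
#'
#' Convenience wrapper: builds the generator at the prevailing Ca2+ level
#' `ca` and, when `ca_init` differs, takes the initial closed-set
#' distribution from the stationary distribution at `ca_init` (the
#' pre-opening equilibrium; see [sample_first_opening_times()]).
#'
#' @inheritParams sample_first_opening_times
#' @return A [dyk_first_opening()] object.
#' @export
dyk_opening_fpt <- function(params, ca = NULL, ca_init = NULL) {
  stopifnot(inherits(params, "cell_params"))
  if (is.null(ca)) ca <- params$ca_base
  if (is.null(ca_init)) ca_init <- params$ca_base
  gen <- build_dyk_generator(params, ca = ca)
  if (isTRUE(all.equal(ca, ca_init))) return(dyk_first_opening(gen))
  gen0 <- build_dyk_generator(params, ca = ca_init)
  init <- dyk_stationary(gen0)$pi[!gen$open]
  dyk_first_opening(gen, init = init)
}

#' Cluster closing (puff termination) density
#'
#' The puff ends when the last of the `n_ch` channels closes; with
#' exponential single-channel closing at rate `lambda_cl` the closing time is
#' the maximum of `n_ch` iid exponentials, i.e. GE(shape = `n_ch`,
#' rate = `lambda_cl`).
#'
#' @param params A [cell_params()].
#' @return A [ge_dist()].
#' @export
make_closing_density <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  ge_dist(shape = params$n_ch, rate = params$lambda_cl)
}
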