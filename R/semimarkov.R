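#' Conditioned waiting times of a semi-Markov chain
#'
#' Builds the matrix of conditioned waiting-time densities
#' `Psi_ij(t)` from the chain's competing transition candidates. Each
#' `Psi_ij` is the sub-density of "the next transition is i -> j and happens
#' at sojourn time t": the basic density of the winning candidate times the
#' survival of all competitors. Rows are normalised by the condition
#' `sum_j integral Psi_ij dt = 1` (non-absorbing states), not individually.
#'
#' @param chain An [sm_chain()].
#' @return Object of class `sm_cwt` carrying the `Psi_ij` closures, the
#'   per-state total sojourn survival, and integration cut-offs.
#' @export
build_conditioned_waiting_times <- function(chain) {
  stopifnot(inherits(chain, "sm_chain"))
  K <- chain$n_states
  transitions <- list()
  surv_total <- vector("list", K)
  tstar <- numeric(K)
  for (i in seq_len(K)) {
    cands <- chain$trans[[i]]
    if (length(cands) == 0) { tstar[i] <- NA_real_; next }
    all_exp <- all(vapply(cands, function(cd) cd$dist$shape == 1, logical(1)))
    G <- local({
      cands_i <- cands
      function(t) {
        s <- rep(1, length(t))
        for (cd in cands_i) s <- s * ge_survival(t, cd$dist)^cd$mult
        s
      }
    })
    surv_total[[i]] <- G
    # integration cut-off: joint survival below 1e-16
    th <- 1
    while (G(th) > 1e-16 && th < 1e12) th <- th * 2
    tstar[i] <- th
    for (idx in seq_along(cands)) {
      cd <- cands[[idx]]
      psi <- local({
        cands_i <- cands; k_win <- idx
        function(t) {
          w <- cands_i[[k_win]]
          out <- w$mult * ge_pdf(t, w$dist)
          if (w$mult > 1) out <- out * ge_survival(t, w$dist)^(w$mult - 1)
          for (m in seq_along(cands_i)) {
            if (m == k_win) next
            out <- out * ge_survival(t, cands_i[[m]]$dist)^cands_i[[m]]$mult
          }
          out
        }
      })
      closed <- NULL
      if (all_exp) {
        R <- sum(vapply(cands, function(x) x$mult * x$dist$rate, numeric(1)))
        closed <- list(r = cd$mult * cd$dist$rate, R = R)
      }
      transitions[[length(transitions) + 1L]] <-
        list(from = i, to = cd$to, psi = psi, exp_form = closed)
    }
  }
  structure(list(n_states = K, state_names = chain$state_names,
                 transitions = transitions, surv_total = surv_total,
                 tstar = tstar, chain = chain),
            class = "sm_cwt")
}

as_cwt <- function(x) {
  if (inherits(x, "sm_cwt")) x
  else if (inherits(x, "sm_chain")) build_conditioned_waiting_times(x)
  else stop("expected an sm_chain or sm_cwt", call. = FALSE)
}

# states are referenced by name (character, e.g. "0".."4" for cluster
# chains) or by 1-based index (numeric)
resolve_state <- function(x, s) {
  nm <- x$state_names
  if (is.character(s)) {
    i <- match(s, nm)
    if (is.na(i)) stop(sprintf("unknown state '%s'", s), call. = FALSE)
    return(i)
  }
  s <- as.integer(s)
  if (!is.na(s) && s >= 1 && s <= length(nm)) return(s)
  stop(sprintf("invalid state index '%s'", s), call. = FALSE)
}

#' Raw-moment table of the conditioned waiting times
#'
#' Computes `m_n(i, j) = integral t^n Psi_ij(t) dt` for `n = 0..order`.
#' These are, up to signs and factorials, the Taylor coefficients of the
#' Laplace transforms `Psi-hat_ij(s)` about `s = 0`; all stationary and
#' first-passage quantities are assembled from them. All-exponential states
#' use the closed form `m_n = r_ij n! / R_i^{n+1}`; otherwise adaptive
#' quadrature on `[0, t*]` with the joint survival below 1e-16 at `t*`.
#'
#' @param x An [sm_chain()] or its `sm_cwt`.
#' @param order Highest moment order (>= 2; >= 4 for kurtosis work).
#' @return A numeric array `[K, K, order + 1]` with dimnames
#'   `(from, to, m0..m<order>)`; `m0` is the embedded transition weight.
#' @export
transform_table <- function(x, order = 4) {
  cwt <- as_cwt(x)
  stopifnot(order >= 0)
  K <- cwt$n_states
  M <- array(0, dim = c(K, K, order + 1),
             dimnames = list(cwt$state_names, cwt$state_names,
                             paste0("m", 0:order)))
  for (tr in cwt$transitions) {
    i <- tr$from; j <- tr$to
    for (n in 0:order) {
      if (!is.null(tr$exp_form)) {
        M[i, j, n + 1] <- tr$exp_form$r * factorial(n) / tr$exp_form$R^(n + 1)
      } else {
        up <- cwt$tstar[i]
        val <- tryCatch(
          stats::integrate(function(t) t^n * tr$psi(t), 0, up,
                           rel.tol = 1e-10, abs.tol = 1e-12,
                           subdivisions = 600L)$value,
          error = function(e)
            stop(sprintf("moment quadrature failed for transition %s -> %s (n = %d): %s",
                         cwt$state_names[i], cwt$state_names[j], n,
                         conditionMessage(e)), call. = FALSE))
        M[i, j, n + 1] <- val
      }
    }
  }
  M
}

embedded_matrix <- function(x, M = NULL) {
  if (is.null(M)) M <- transform_table(x, order = 1)
  M[, , 1]
}

reachable_from <- function(P, i) {
  K <- nrow(P)
  seen <- logical(K); seen[i] <- TRUE
  frontier <- i
  while (length(frontier)) {
    nxt <- which(colSums(P[frontier, , drop = FALSE] > 0) > 0)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Stationary occupancy probabilities
#'
#' The stationary probability of each observable state, obtained from the
#' `s -> 0` limit of the Laplace-domain flux system (final-value theorem):
#' `pi_i` is proportional to `v_i tau_i`, where `v` is the stationary vector
#' of the embedded jump chain (`v = vP`, `P` the matrix of transition
#' weights) and `tau_i = sum_j m_1(i, j)` is the mean sojourn time in `i`.
#'
#' @param x An [sm_chain()] or `sm_cwt`.
#' @return Named numeric vector summing to 1.
#' @export
stationary_occupancy <- function(x) {
  cwt <- as_cwt(x)
  M <- transform_table(cwt, order = 1)
  P <- M[, , 1]
  K <- cwt$n_states
  rs <- rowSums(P)
  if (any(rs < 1e-12))
    stop("stationary occupancy undefined: absorbing state(s) ",
         paste(cwt$state_names[rs < 1e-12], collapse = ", "), call. = FALSE)
  if (!all(reachable_from(P, 1)))
    stop("embedded chain reducible; unreachable state(s): ",
         paste(cwt$state_names[!reachable_from(P, 1)], collapse = ", "),
         call. = FALSE)
  A <- t(P) - diag(K)
  A[K, ] <- 1
  v <- solve(A, c(rep(0, K - 1), 1))
  tau <- rowSums(M[, , 2])
  pi <- v * tau
  pi <- pi / sum(pi)
  names(pi) <- cwt$state_names
  pi
}

fpt_summary_from_moments <- function(m) {
  m1 <- m[1]; m2 <- m[2]; m3 <- m[3]; m4 <- m[4]
  v <- m2 - m1^2
  s <- sqrt(v)
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  structure(list(moments = stats::setNames(m, paste0("m", seq_along(m))),
                 mean = unname(m1), sd = unname(s), cv = unname(s / m1),
                 skewness = unname(mu3 / s^3),
                 excess_kurtosis = unname(mu4 / v^2 - 3)),
            class = "fpt_summary")
}

#' @export
print.fpt_summary <- function(x, ...) {
  cat(sprintf("First-passage / ISI statistics:\n"))
  cat(sprintf("  T_av = %.6g s, sd = %.6g s, CV = %.4f\n", x$mean, x$sd, x$cv))
  cat(sprintf("  skewness = %.4f, excess kurtosis = %.4f\n",
              x$skewness, x$excess_kurtosis))
  if (!is.null(x$se))
    cat(sprintf("  bootstrap SE: mean %.3g, sd %.3g, cv %.3g\n",
                x$se["mean"], x$se["sd"], x$se["cv"]))
  invisible(x)
}

#' First-passage-time (interspike-interval) moments
#'
#' Raw moments `<T^n>` of the first-passage time from `start` to `target`,
#' computed in the Laplace domain: with the target made absorbing, the
#' transforms of the first-passage densities satisfy the linear system
#' `F_i(s) = Psi-hat_{i,target}(s) + sum_{j != target} Psi-hat_ij(s) F_j(s)`,
#' which is solved order by order in the Taylor expansion about `s = 0`
#' (truncated power-series arithmetic; only `s = 0` derivatives are needed,
#' so no inverse transform is required). `<T^n> = (-1)^n n! f_n(start)`.
#' The construction conditions on a fresh entry into `start` at `t = 0`
#' (renewal start), so for a cluster chain `fpt_moments(x, "0", "N")` is the
#' ISI distribution of the spike process.
#'
#' @param x An [sm_chain()] or `sm_cwt`.
#' @param start,target State names or indices; must differ.
#' @param n_max Highest moment (default 4).
#' @return An `fpt_summary`: raw moments `m1..m<n_max>`, mean `T_av`, sd,
#'   CV, skewness and excess kurtosis (the last two only when `n_max >= 4`).
#' @export
fpt_moments <- function(x, start, target, n_max = 4) {
  cwt <- as_cwt(x)
  i0 <- resolve_state(cwt, start)
  tg <- resolve_state(cwt, target)
  if (i0 == tg) stop("'start' and 'target' must differ", call. = FALSE)
  M <- transform_table(cwt, order = n_max)
  P <- M[, , 1]
  if (!reachable_from(P, i0)[tg])
    stop(sprintf("target state '%s' not reachable from '%s'",
                 cwt$state_names[tg], cwt$state_names[i0]), call. = FALSE)
  nt <- setdiff(seq_len(cwt$n_states), tg)
  # Taylor coefficients of Psi-hat: C_n = (-1)^n m_n / n!
  Cn <- lapply(0:n_max, function(n) (-1)^n * M[, , n + 1] / factorial(n))
  A0 <- diag(length(nt)) - Cn[[1]][nt, nt, drop = FALSE]
  lu <- tryCatch(solve(A0), error = function(e)
    stop("first-passage system singular: no finite moments (no path?)",
         call. = FALSE))
  Fn <- vector("list", n_max + 1)
  for (n in 0:n_max) {
    rhs <- Cn[[n + 1]][nt, tg]
    if (n > 0) {
      for (k in 1:n)
        rhs <- rhs + Cn[[k + 1]][nt, nt, drop = FALSE] %*% Fn[[n - k + 1]]
    }
    Fn[[n + 1]] <- lu %*% rhs
  }
  pos <- match(i0, nt)
  hit <- Fn[[1]][pos]
  if (abs(hit - 1) > 1e-6)
    warning(sprintf("first-passage probability is %.8f (< 1): defective density",
                    hit))
  m <- vapply(1:n_max, function(n) (-1)^n * factorial(n) * Fn[[n + 1]][pos],
              numeric(1))
  if (any(!is.finite(m)) || m[1] <= 0)
    stop("non-finite first-passage moments", call. = FALSE)
  out <- if (n_max >= 4) fpt_summary_from_moments(m[1:4]) else {
    v <- m[2] - m[1]^2
    structure(list(moments = stats::setNames(m, paste0("m", 1:n_max)),
                   mean = m[1], sd = sqrt(v), cv = sqrt(v) / m[1],
                   skewness = NA_real_, excess_kurtosis = NA_real_),
              class = "fpt_summary")
  }
  if (n_max > 4) out$moments <- stats::setNames(m, paste0("m", 1:n_max))
  out$hit_probability <- unname(hit)
  out
}

#' Splitting probability on a birth-death section
#'
#' Probability of reaching state `up` before state `down`, starting from
#' `from`, computed from the one-step embedded weights by the gambler's-ruin
#' product formula. For the cluster chain with `from = 1`, `up = N`,
#' `down = 0` this is the coupling strength: the probability that a single
#' puff escalates into a global spike.
#'
#' @param x An [sm_chain()] or `sm_cwt`.
#' @param from,up,down State names or indices with `down < from < up` along
#'   a birth-death (nearest-neighbour) section of the chain.
#' @return A probability.
#' @export
splitting_probability <- function(x, from, up, down) {
  cwt <- as_cwt(x)
  i <- resolve_state(cwt, from)
  u <- resolve_state(cwt, up)
  d <- resolve_state(cwt, down)
  if (!(d < i && i < u))
    stop("'from' must lie strictly between 'down' and 'up'", call. = FALSE)
  P <- embedded_matrix(cwt)
  inner <- (d + 1):(u - 1)
  for (k in inner) {
    nb <- which(P[k, ] > 0)
    if (!all(nb %in% c(k - 1L, k + 1L)))
      stop("splitting probability requires birth-death topology between 'down' and 'up'",
           call. = FALSE)
  }
  # p_k = up-step weight of state k, q_k = down-step weight
  p <- vapply(inner, function(k) P[k, k + 1L], numeric(1))
  q <- vapply(inner, function(k) P[k, k - 1L], numeric(1))
  r <- q / p
  cum <- cumprod(r)
  denom <- 1 + sum(cum)
  numer <- 1 + if (i - d - 1 >= 1) sum(cum[seq_len(i - d - 1)]) else 0
  numer / denom
}
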