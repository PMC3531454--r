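#' Semi-Markov chain over observable states
#'
#' A chain is a set of observable states with, per state, a list of competing
#' transition candidates. Each candidate is a basic waiting-time density
#' (a [ge_dist()]) with a multiplicity `mult`: `mult` independent copies
#' compete (e.g. the `N - i` closed clusters that could open). The conditioned
#' waiting times of the process are the competing-risks products
#' \deqn{\Psi_{ij}(t) = m_j f_j(t) S_j(t)^{m_j - 1} \prod_{k \ne j} S_k(t)^{m_k}.}
#'
#' @param trans List (one element per state) of candidate lists; each
#'   candidate is `list(to = <state index>, dist = <ge_dist>, mult = <int>)`.
#'   A state with no candidates is absorbing.
#' @param state_names Optional character labels (default `"1"..."K"`).
#' @param target_state Optional spike/target state index (metadata used by
#'   simulation helpers).
#' @return An object of class `sm_chain`.
#' @seealso [spike_chain()] for the cluster-chain constructor,
#'   [make_fixture_chain()] for small exponential test chains.
#' @export
sm_chain <- function(trans, state_names = NULL, target_state = NULL) {
  K <- length(trans)
  if (K < 2) stop("need at least 2 states", call. = FALSE)
  for (i in seq_len(K)) {
    for (cand in trans[[i]]) {
      if (!is.list(cand) || is.null(cand$to) || is.null(cand$dist))
        stop("each candidate needs 'to' and 'dist'", call. = FALSE)
      if (!inherits(cand$dist, "ge_dist"))
        stop("candidate densities must be ge_dist objects", call. = FALSE)
      if (cand$to < 1 || cand$to > K || cand$to == i)
        stop(sprintf("invalid transition target from state %d", i),
             call. = FALSE)
    }
  }
  trans <- lapply(trans, function(cl)
    lapply(cl, function(cand) {
      if (is.null(cand$mult)) cand$mult <- 1L
      cand$mult <- as.integer(cand$mult)
      stopifnot(cand$mult >= 1L)
      cand
    }))
  if (is.null(state_names)) state_names <- as.character(seq_len(K))
  stopifnot(length(state_names) == K)
  structure(list(n_states = K, trans = trans, state_names = state_names,
                 target_state = target_state),
            class = "sm_chain")
}

#' @export
print.sm_chain <- function(x, ...) {
  cat(sprintf("Semi-Markov chain with %d states: %s\n", x$n_states,
              paste(x$state_names, collapse = " ")))
  for (i in seq_len(x$n_states)) {
    for (cand in x$trans[[i]]) {
      cat(sprintf("  %s -> %s : %d x GE(a = %g, lambda = %g s^-1)\n",
                  x$state_names[i], x$state_names[cand$to], cand$mult,
                  cand$dist$shape, cand$dist$rate))
    }
    if (length(x$trans[[i]]) == 0)
      cat(sprintf("  %s : absorbing\n", x$state_names[i]))
  }
  invisible(x)
}

#' Cluster-chain (spike) model
#'
#' Builds the observable chain over `0..N` open clusters. The transition out
#' of the ground state (all clusters closed) is a pure exponential puff
#' density; for `i >= 1` open clusters each of the remaining `N - i` closed
#' clusters competes to open with density `open_dist` (the CICR-accelerated
#' opening density at the elevated local Ca2+) and each of the `i` open
#' clusters competes to close with density `close_dist`. A spike is the entry
#' into `target_state` (default `N`, all clusters open).
#'
#' @param n_clusters Number of clusters `N >= 2`.
#' @param puff_rate Total rate of the 0 -> 1 transition, s^-1.
#' @param open_dist A [ge_dist()]: single-cluster opening density given at
#'   least one cluster open. May also be a list of length `N - 1` with one
#'   density per occupancy level 1..N-1.
#' @param close_dist A [ge_dist()]: single-cluster (puff) closing density.
#' @param target_state Spike definition, state in `1..N`; default `N`.
#' @return An `sm_chain` with states named `"0".."N"`.
#' @examples
#' ch <- spike_chain(4, puff_rate = 0.05, open_dist = ge_dist(2, 5),
#'                   close_dist = ge_dist(5, 50))
#' fpt_moments(ch, start = "0", target = "4")
#' @export
spike_chain <- function(n_clusters, puff_rate, open_dist, close_dist,
                        target_state = n_clusters) {
  N <- n_clusters
  stopifnot(N >= 2, puff_rate > 0, inherits(close_dist, "ge_dist"))
  if (inherits(open_dist, "ge_dist"))
    open_dist <- rep(list(open_dist), N - 1)
  stopifnot(length(open_dist) == N - 1)
  if (target_state < 1 || target_state > N)
    stop("'target_state' must lie in 1..n_clusters", call. = FALSE)
  trans <- vector("list", N + 1)
  trans[[1]] <- list(list(to = 2L, dist = exp_dist(puff_rate), mult = 1L))
  for (i in 1:(N - 1)) {
    trans[[i + 1]] <- list(
      list(to = i + 2L, dist = open_dist[[i]], mult = N - i),
      list(to = i, dist = close_dist, mult = i))
  }
  trans[[N + 1]] <- list(list(to = N, dist = close_dist, mult = N))
  ch <- sm_chain(trans, state_names = as.character(0:N),
                 target_state = target_state + 1L)
  ch$n_clusters <- N
  ch
}

#' Small fixture chains with known closed-form answers
#'
#' Markov-limit (all-exponential) chains used throughout the test suites:
#' `two_state`, forward-only `erlang` stages, a random `birth_death` chain,
#' and the all-exponential tetrahedron `tetrahedron_exp`.
#'
#' @param kind One of `"two_state"`, `"erlang"`, `"birth_death"`,
#'   `"tetrahedron_exp"`.
#' @param params Named list of kind-specific parameters: `two_state` takes
#'   `k12`, `k21`; `erlang` takes `n_stages`, `rate`; `birth_death` takes
#'   `n_states` and optionally `up`, `down` rate vectors (random if missing);
#'   `tetrahedron_exp` takes `puff_rate`, `k_open`, `k_close`.
#' @param seed Optional seed for randomized rates (`birth_death`).
#' @return An `sm_chain`.
#' @export
make_fixture_chain <- function(kind = c("two_state", "erlang", "birth_death",
                                        "tetrahedron_exp"),
                               params = list(), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  switch(kind,
    two_state = {
      k12 <- p$k12 %||% 1; k21 <- p$k21 %||% 2
      sm_chain(list(list(list(to = 2L, dist = exp_dist(k12))),
                    list(list(to = 1L, dist = exp_dist(k21)))))
    },
    erlang = {
      n <- p$n_stages %||% 3; r <- p$rate %||% 1
      trans <- c(lapply(seq_len(n), function(i)
        list(list(to = i + 1L, dist = exp_dist(r)))), list(list()))
      sm_chain(trans)
    },
    birth_death = {
      n <- p$n_states %||% 5
      up <- p$up %||% stats::runif(n - 1, 0.5, 5)
      down <- p$down %||% stats::runif(n - 1, 0.5, 5)
      trans <- vector("list", n)
      for (i in seq_len(n)) {
        cl <- list()
        if (i < n) cl <- c(cl, list(list(to = i + 1L, dist = exp_dist(up[i]))))
        if (i > 1) cl <- c(cl, list(list(to = i - 1L,
                                         dist = exp_dist(down[i - 1]))))
        trans[[i]] <- cl
      }
      sm_chain(trans)
    },
    tetrahedron_exp = {
      spike_chain(4, puff_rate = p$puff_rate %||% 0.05,
                  open_dist = exp_dist(p$k_open %||% 5),
                  close_dist = exp_dist(p$k_close %||% 20))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
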