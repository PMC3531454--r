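# Independent oracles used across the suites.

# CTMC generator of an all-exponential semi-Markov chain
chain_generator <- function(chain) {
  K <- chain$n_states
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (cd in chain$trans[[i]]) {
      stopifnot(cd$dist$shape == 1)
      Q[i, cd$to] <- Q[i, cd$to] + cd$mult * cd$dist$rate
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of a CTMC (balance equations)
ctmc_stationary <- function(Q) {
  K <- nrow(Q)
  A <- t(Q); A[K, ] <- 1
  solve(A, c(rep(0, K - 1), 1))
}

# raw FPT moments start -> target via the fundamental matrix:
# h_n = n (-Q_sub)^{-1} h_{n-1}, h_0 = 1
ctmc_fpt_moments <- function(Q, start, target, n_max = 4) {
  Qs <- Q[-target, -target, drop = FALSE]
  idx <- match(start, setdiff(seq_len(nrow(Q)), target))
  h <- rep(1, nrow(Qs))
  vapply(seq_len(n_max), function(n) {
    h <<- n * solve(-Qs, h)
    h[idx]
  }, numeric(1))
}

# Laplace transform of a GE density with integer shape via the finite
# exponential-sum expansion (binomial theorem on (1 - e^{-lt})^{a-1})
ge_laplace_expansion <- function(s, a, lam) {
  stopifnot(a == round(a))
  k <- 0:(a - 1)
  sum(a * lam * choose(a - 1, k) * (-1)^k / (s + (k + 1) * lam))
}

# vectorized gambler's-ruin walk: start at `from`, absorb at `down`/`up`,
# one-step up-probabilities p[state] indexed by the inner states
ruin_walk <- function(p_up, from, up, down, n_walk, seed) {
  set.seed(seed)
  state <- rep.int(from, n_walk)
  alive <- rep(TRUE, n_walk)
  won <- logical(n_walk)
  while (any(alive)) {
    u <- runif(sum(alive))
    s <- state[alive]
    s <- s + ifelse(u < p_up[s - down], 1L, -1L)
    state[alive] <- s
    won[alive][s == up] <- TRUE
    alive[alive] <- s != up & s != down
  }
  mean(won)
}

# standard GE tetrahedron used in the analytic/simulation comparisons:
# exponential puff input, GE opening and closing densities
ge_tetrahedron <- function(puff_rate = 0.4, open = ge_dist(2.2, 48),
                           close = ge_dist(5, 50)) {
  spike_chain(4, puff_rate = puff_rate, open_dist = open, close_dist = close)
}
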