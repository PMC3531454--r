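test_that("conditioned waiting times: embedded weights and Markov limit", {
  # competing exponentials: p[i][i+1] = (N-i) k_o / ((N-i) k_o + i k_c)
  ch <- make_fixture_chain("tetrahedron_exp",
                           list(puff_rate = 0.3, k_open = 5, k_close = 20))
  M <- transform_table(ch, order = 1)
  P <- M[, , 1]
  N <- 4; ko <- 5; kc <- 20
  for (i in 1:3)
    expect_equal(P[i + 1, i + 2], (N - i) * ko / ((N - i) * ko + i * kc),
                 tolerance = 1e-12)
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-8)
})

test_that("embedded rows of a GE chain are normalised by the condition", {
  ch <- ge_tetrahedron()
  M <- transform_table(ch, order = 2)
  P <- M[, , 1]
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-8)
  # sub-densities: every m0 in (0, 1]; Cauchy-Schwarz per transition
  on <- which(P > 0)
  expect_true(all(P[on] > 0 & P[on] <= 1 + 1e-12))
  m1 <- M[, , 2][on]; m2 <- M[, , 3][on]
  expect_true(all(m1^2 <= P[on] * m2 + 1e-14))
  # conditioned 1 -> 2 transition is much faster than the puff transition
  t01 <- M["0", "1", 2] / M["0", "1", 1]
  t12 <- M["1", "2", 2] / M["1", "2", 1]
  expect_lt(t12 * 50, t01)
})

test_that("moment table matches the Beta-transform derivatives for GE input", {
  # single GE transition, no competitors: m_n from quadrature must agree
  # with (-1)^n times the n-th derivative of a B(1 + s/l, a) at s = 0
  d <- ge_dist(2.2, 48)
  ch <- sm_chain(list(list(list(to = 2L, dist = d)), list()))
  M <- transform_table(ch, order = 4)
  h <- 1e-3
  lap <- function(s) ge_laplace(s, d)
  d1 <- -(lap(h) - lap(-h)) / (2 * h)
  d2 <- (lap(h) - 2 * lap(0) + lap(-h)) / h^2
  expect_equal(M[1, 2, 1], 1, tolerance = 1e-9)
  expect_equal(M[1, 2, 2], d1, tolerance = 1e-5)
  expect_equal(M[1, 2, 3], d2, tolerance = 1e-4)
  # exponential closed form m_n = n!/k^n
  che <- sm_chain(list(list(list(to = 2L, dist = exp_dist(3))), list()))
  Me <- transform_table(che, order = 4)
  expect_equal(Me[1, 2, ], factorial(0:4) / 3^(0:4), ignore_attr = TRUE)
})

test_that("stationary occupancy reproduces CTMC balance and symmetry", {
  expect_equal(unname(stationary_occupancy(
    make_fixture_chain("two_state", list(k12 = 1, k21 = 2)))),
    c(2, 1) / 3, tolerance = 1e-10)
  # symmetric two-state chain with identical GE sojourns
  d <- ge_dist(3.3, 2)
  sym <- sm_chain(list(list(list(to = 2L, dist = d)),
                       list(list(to = 1L, dist = d))))
  expect_equal(unname(stationary_occupancy(sym)), c(0.5, 0.5),
               tolerance = 1e-9)
  expect_error(stationary_occupancy(make_fixture_chain("erlang")), "absorbing")
})

test_that("Markov-limit equivalence on randomized birth-death chains", {
  for (seed in c(3, 17, 29)) {
    n <- sample(3:6, 1)
    ch <- make_fixture_chain("birth_death", list(n_states = n), seed = seed)
    Q <- chain_generator(ch)
    expect_equal(unname(stationary_occupancy(ch)), ctmc_stationary(Q),
                 tolerance = 1e-6)
    mo <- ctmc_fpt_moments(Q, 1, n)
    f <- fpt_moments(ch, 1, n)
    expect_equal(unname(f$moments[1:4]), mo, tolerance = 1e-6)
  }
})

test_that("first-passage summaries match exponential and Erlang closed forms", {
  two <- sm_chain(list(list(list(to = 2L, dist = exp_dist(4))), list()))
  s <- fpt_moments(two, 1, 2)
  expect_equal(s$mean, 1 / 4, tolerance = 1e-10)
  expect_equal(s$cv, 1, tolerance = 1e-10)
  expect_equal(s$skewness, 2, tolerance = 1e-9)
  expect_equal(s$excess_kurtosis, 6, tolerance = 1e-9)
  er <- make_fixture_chain("erlang", list(n_stages = 2, rate = 3))
  s2 <- fpt_moments(er, 1, 3)
  expect_equal(s2$mean, 2 / 3, tolerance = 1e-10)
  expect_equal(s2$cv, 1 / sqrt(2), tolerance = 1e-10)
  er3 <- make_fixture_chain("erlang", list(n_stages = 3, rate = 1))
  s3 <- fpt_moments(er3, 1, 4)
  expect_equal(s3$mean, 3, tolerance = 1e-10)
  expect_equal(s3$cv, 1 / sqrt(3), tolerance = 1e-10)
  expect_error(fpt_moments(er, 3, 1), "not reachable")
  expect_error(fpt_moments(er, 2, 2), "must differ")
})

test_that("exponential limit: slow puff input drives ISI to exponential shape", {
  base <- list(k_open = 5, k_close = 20)
  rates <- c(1, 0.1, 0.01)
  cvs <- sapply(rates, function(r) {
    ch <- make_fixture_chain("tetrahedron_exp", c(base, puff_rate = r))
    s <- fpt_moments(ch, "0", "4")
    c(s$cv, s$skewness, s$excess_kurtosis)
  })
  # approach (1, 2, 6) monotonically as the 0 -> 1 rate shrinks
  expect_true(all(diff(abs(cvs[1, ] - 1)) < 0))
  expect_equal(cvs[1, 3], 1, tolerance = 1e-3)
  expect_equal(cvs[2, 3], 2, tolerance = 5e-3)
  expect_equal(cvs[3, 3], 6, tolerance = 2e-2)
})

test_that("splitting probabilities follow the gambler's-ruin formula", {
  bd <- make_fixture_chain("birth_death",
                           list(n_states = 5, up = rep(1, 4), down = rep(1, 4)))
  expect_equal(splitting_probability(bd, 2, 5, 1), 0.25, tolerance = 1e-12)
  # all-up chain
  fw <- make_fixture_chain("birth_death",
                           list(n_states = 5, up = rep(1, 4),
                                down = rep(1e-14, 4)))
  expect_equal(splitting_probability(fw, 2, 5, 1), 1, tolerance = 1e-10)
  # arbitrary one-step weights vs a Monte-Carlo ruin walk
  p_up <- c(0.7, 0.8, 0.9)  # up-step weights of the three inner states
  bd_chain <- function(p) make_fixture_chain(
    "birth_death", list(n_states = 5, up = c(1, p / (1 - p)),
                        down = rep(1, 4)))
  ch <- bd_chain(p_up)
  ana <- splitting_probability(ch, 2, 5, 1)
  n_walk <- 2e5
  mc <- ruin_walk(p_up, from = 2, up = 5, down = 1, n_walk = n_walk,
                  seed = 99)
  se <- sqrt(ana * (1 - ana) / n_walk)
  expect_lt(abs(mc - ana), 3 * se)
  # monotone non-decreasing in each one-step weight
  for (k in 1:3) {
    p2 <- p_up; p2[k] <- p2[k] + 0.05
    expect_gte(splitting_probability(bd_chain(p2), 2, 5, 1), ana)
  }
  expect_error(splitting_probability(bd, 1, 5, 1), "strictly between")
})
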