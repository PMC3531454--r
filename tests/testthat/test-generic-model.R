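test_that("spike intensity: zero at the origin, saturating, additive", {
  p <- generic_params(0.1, 0.5, rho = 0.02, n_clusters = 4)
  expect_equal(spike_intensity(0, p), 0)
  expect_equal(spike_intensity(1e6, p), 4 * 0.5 * 0.1, tolerance = 1e-12)
  expect_true(all(diff(spike_intensity(seq(0, 300, 5), p)) > 0))
  # no feedback: constant total spike rate
  pInf <- generic_params(0.1, 0.5, rho = Inf, n_clusters = 4)
  expect_equal(spike_intensity(c(0, 3, 100), pInf), rep(0.2, 3))
  # heterogeneous clusters sum their contributions
  ph <- generic_params(c(0.1, 0.2), c(1, 0.5), rho = Inf)
  expect_equal(ph$lambda_inf, 0.2)
  expect_error(generic_params(0.1, 1.5, 1), "couplings")
})

test_that("generic ISI density normalises and has the closed exponential limit", {
  for (par in list(c(0.02, 0.05), c(0.1, 0.01), c(0.5, 1))) {
    p <- generic_params(par[1], 1, rho = par[2], n_clusters = 1)
    expect_equal(p$lambda_inf, par[1])
    expect_equal(isi_density_generic(0, p), 0)
    thi <- 60 / p$lambda_inf + 10 / p$rho
    expect_equal(integrate(function(t) isi_density_generic(t, p), 0, thi,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  }
  pInf <- generic_params(0.02, 1, rho = Inf, n_clusters = 1)
  tt <- c(0.5, 10, 80)
  expect_equal(isi_density_generic(tt, pInf), 0.02 * exp(-0.02 * tt))
})

test_that("generic moments: exponential limit, refractory delay, cv bounds", {
  pInf <- generic_params(0.02, 1, rho = Inf, n_clusters = 1)
  s <- generic_moments(pInf)
  expect_equal(s$mean, 50)
  expect_equal(s$sd, 50)
  expect_equal(s$cv, 1, tolerance = 1e-12)
  # finite recovery delays spikes and regularises the train
  lam <- 0.05
  cvs <- sapply(c(0.005, 0.02, 0.1, 1), function(r) {
    g <- generic_moments(generic_params(lam, 1, rho = r, n_clusters = 1))
    expect_gt(g$mean, 1 / lam)
    g$cv
  })
  expect_true(all(cvs < 1))
  expect_true(all(diff(cvs) > 0))  # cv increases with rho towards 1
  # T_av decreases in lambda_inf and in rho
  tav_l <- sapply(c(0.01, 0.02, 0.05), function(l)
    generic_moments(generic_params(l, 1, 0.05, 1))$mean)
  expect_true(all(diff(tav_l) < 0))
  tav_r <- sapply(c(0.01, 0.05, 0.5), function(r)
    generic_moments(generic_params(0.05, 1, r, 1))$mean)
  expect_true(all(diff(tav_r) < 0))
})

test_that("generic sampling matches the analytic moments and cv ordering", {
  pInf <- generic_params(0.05, 1, rho = Inf, n_clusters = 1)
  trI <- sample_generic_train(pInf, 8000, seed = 4)
  expect_equal(sd(trI$isis) / mean(trI$isis), 1, tolerance = 0.05)
  p <- generic_params(1, 1, rho = 1, n_clusters = 1)
  tr <- sample_generic_train(p, 10000, seed = 6)
  g <- generic_moments(p)
  se <- sd(tr$isis) / sqrt(length(tr$isis))
  expect_lt(abs(mean(tr$isis) - g$mean), 3 * se)
  # thinning cross-check of the hazard-inversion sampler
  set.seed(11)
  lam_max <- p$lambda_inf
  thin <- replicate(4000, {
    t <- 0
    repeat {
      t <- t - log(runif(1)) / lam_max
      if (runif(1) < spike_intensity(t, p) / lam_max) break
    }
    t
  })
  expect_lt(abs(mean(thin) - g$mean),
            3 * (sd(thin) / sqrt(length(thin)) + se))
  # stronger feedback (smaller rho) lowers the sampled cv below 1
  tr2 <- sample_generic_train(generic_params(1, 1, rho = 0.2, n_clusters = 1),
                              8000, seed = 7)
  cv2 <- sd(tr2$isis) / mean(tr2$isis)
  expect_lt(cv2, sd(tr$isis) / mean(tr$isis))
  expect_lt(cv2, 1)
})

test_that("sigma-T_av relation: unit slope without feedback, flatter with it", {
  relInf <- moment_relation(seq(0.005, 0.05, length.out = 8), rho = Inf)
  expect_equal(relInf$slope, 1, tolerance = 1e-6)
  expect_equal(relInf$intercept_s, 0, tolerance = 1e-6)
  # changing the coupling strength only rescales lambda_inf, so cells with
  # xi in {0.05, 0.01, 0.008} (cluster puff rate 0.4 s^-1, 4 clusters) all
  # lie on one near-linear relation whose slope xi does not affect
  lam <- 0.4
  xis <- c(0.05, 0.01, 0.008)
  grid <- sort(c(4 * lam * xis, 4 * lam * c(0.02, 0.035)))
  rel <- moment_relation(grid, rho = 0.01)
  # refractory recovery flattens the relation below the Poisson slope of 1
  # (the offset produces an intrinsic minimal ISI rather than sigma = T_av)
  expect_lt(rel$slope, 0.98)
  resid <- rel$points$sigma_s -
    (rel$intercept_s + rel$slope * rel$points$t_av_s)
  expect_lt(max(abs(resid)) / mean(rel$points$sigma_s), 0.05)
  for (xi in xis) {
    s <- generic_moments(generic_params(lam, xi, rho = 0.01, n_clusters = 4))
    pred <- rel$intercept_s + rel$slope * s$mean
    expect_equal(s$sd, pred, tolerance = 0.05)
  }
  # rescaling every lambda_inf by a common xi leaves the slope unchanged
  rel2 <- moment_relation(grid * 0.7, rho = 0.01)
  expect_equal(rel2$slope, rel$slope, tolerance = 0.15)
  expect_error(moment_relation(c(0.01, 0.02), rho = 1), "5 sweep points")
})

test_that("coupling strength and intrinsic minimal ISI from the chain maps", {
  map <- default_param_map()
  # xi saturates in IP3 and in n_ch
  ip3 <- c(0.05, 0.1, 0.3, 1, 3, 8)
  xi_ip3 <- sapply(ip3, function(v)
    coupling_from_mechanistic(spike_chain_from_map(cell_params(ip3 = v), map)))
  expect_true(all(diff(xi_ip3) > 0))
  expect_lt(xi_ip3[6] - xi_ip3[5], 0.05 * xi_ip3[6])  # plateau
  nch <- c(2, 3, 5, 7, 10)
  xi_nch <- sapply(nch, function(n)
    coupling_from_mechanistic(spike_chain_from_map(cell_params(n_ch = n), map)))
  expect_true(all(diff(xi_nch) > 0))
  expect_lt(xi_nch[5], 1)
  expect_gt(xi_nch[5], 0.95)  # saturation only at high channel numbers
  # saturation of both xi and the puff rate bounds T_av away from zero
  tav <- sapply(ip3, function(v)
    fpt_moments(spike_chain_from_map(cell_params(ip3 = v), map),
                "0", "4", n_max = 2)$mean)
  expect_true(all(tav > 1))
  expect_lt(tav[5] - tav[6], 0.05 * tav[6])
  # trivial coupling cases
  allup <- make_fixture_chain("birth_death",
                              list(n_states = 5, up = rep(1, 4),
                                   down = rep(1e-14, 4)))
  allup$target_state <- 5L
  expect_equal(coupling_from_mechanistic(allup), 1, tolerance = 1e-10)
})

test_that("generic approximation error is small and grows with failed puffs", {
  # exponential tetrahedra with decreasing coupling: the neglected excursion
  # time per spike grows linearly in (1-xi)/xi
  ks <- c(2, 5, 10, 20, 40)
  chains <- lapply(ks, function(k)
    make_fixture_chain("tetrahedron_exp",
                       list(puff_rate = 0.05, k_open = 5, k_close = k)))
  err <- approximation_error(chains)
  expect_true(all(diff(err$xi) < 0))
  expect_true(all(diff(err$abs_error_s) > 0))
  fit <- lm(abs_error_s ~ failed_puffs, err)
  expect_gt(summary(fit)$r.squared, 0.9)
  # vanishing error when every puff spikes and excursions are negligible
  fast <- spike_chain(4, puff_rate = 0.01, open_dist = exp_dist(5000),
                      close_dist = exp_dist(5))
  e1 <- approximation_error(fast)
  expect_gt(e1$xi, 0.995)
  expect_lt(e1$rel_error, 0.01)
})
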