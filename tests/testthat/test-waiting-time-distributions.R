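test_that("GE density, survival and quantile match closed-form values", {
  # exponential special case at the origin
  expect_equal(ge_pdf(0, ge_dist(1, 1)), 1)
  # shape > 1 vanishes at the origin
  expect_equal(ge_pdf(1e-12, ge_dist(2, 1)), 0, tolerance = 1e-9)
  # direct evaluation at t = ln 2: 2 * (1/2) * (1/2)
  expect_equal(ge_pdf(log(2), ge_dist(2, 1)), 0.5, tolerance = 1e-12)
  expect_equal(ge_survival(0, ge_dist(3.7, 2.2)), 1)
  expect_equal(ge_survival(0.9, ge_dist(1, 1.7)), exp(-1.7 * 0.9))
  expect_equal(ge_survival(log(2), ge_dist(2, 1)), 0.75, tolerance = 1e-12)
  # survival stays stable deep in the tail (log-domain evaluation)
  s <- ge_survival(c(50, 80, 120), ge_dist(3, 1))
  expect_true(all(s > 0) && all(diff(s) < 0))
  expect_equal(ge_cdf(ge_quantile(0.37, ge_dist(2.5, 3)), ge_dist(2.5, 3)),
               0.37, tolerance = 1e-12)
  expect_error(ge_dist(0, 1), "shape")
  expect_error(ge_dist(2, -1), "rate")
})

test_that("GE Laplace transform equals the Beta form and its special cases", {
  expect_equal(ge_laplace(0, ge_dist(4.2, 7)), 1, tolerance = 1e-12)
  # exponential case lambda / (lambda + s)
  expect_equal(ge_laplace(2.5, ge_dist(1, 3)), 3 / 5.5, tolerance = 1e-12)
  # a = 2, lambda = 1, s = 1: finite exponential-sum gives 1/3
  expect_equal(ge_laplace(1, ge_dist(2, 1)), 1 / 3, tolerance = 1e-12)
  # integer shapes agree with the exponential-sum expansion
  for (a in c(2, 3, 5)) {
    for (s in c(0.1, 1, 10)) {
      expect_equal(ge_laplace(s, ge_dist(a, 2)),
                   ge_laplace_expansion(s, a, 2), tolerance = 1e-10)
    }
  }
  # complex argument agrees with the real axis and with quadrature
  z <- ge_laplace(1 + 2i, ge_dist(2, 1))
  zq <- integrate(function(t) ge_pdf(t, ge_dist(2, 1)) * cos(2 * t) * exp(-t),
                  0, 60, rel.tol = 1e-12)$value
  expect_equal(Re(z), zq, tolerance = 1e-8)
  expect_error(ge_laplace(-5, ge_dist(2, 1)), "1 \\+ Re")
})

test_that("GE moments: digamma mean, order statistics, quadrature identity", {
  expect_equal(ge_moment(0, ge_dist(9, 0.3)), 1)
  expect_equal(ge_moment(1, ge_dist(1, 2)), 0.5)
  # max of two iid Exp(1): 1 + 1/2
  expect_equal(ge_moment(1, ge_dist(2, 1)), 1.5, tolerance = 1e-10)
  # harmonic-number mean for integer shape
  expect_equal(ge_moment(1, ge_dist(5, 50)), sum(1 / (1:5)) / 50,
               tolerance = 1e-10)
  # mean identity vs direct quadrature; normalisation for assorted shapes
  for (par in list(c(0.7, 0.5), c(1, 3), c(2.8, 10), c(6, 0.2))) {
    d <- ge_dist(par[1], par[2])
    q <- integrate(function(t) t * ge_pdf(t, d), 0,
                   ge_quantile(1 - 1e-13, d) * 2, rel.tol = 1e-10)$value
    expect_equal(ge_moment(1, d), q, tolerance = 1e-6)
    expect_equal(integrate(function(t) ge_pdf(t, d), 0,
                           ge_quantile(1 - 1e-13, d) * 2,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  }
  # moments match (-1)^n d^n/ds^n of the transform at s = 0 (central diff)
  d <- ge_dist(2.5, 3)
  h <- 1e-3
  num1 <- -(ge_laplace(h, d) - ge_laplace(-h, d)) / (2 * h)
  expect_equal(ge_moment(1, d), num1, tolerance = 1e-5)
  num2 <- (ge_laplace(h, d) - 2 * ge_laplace(0, d) + ge_laplace(-h, d)) / h^2
  expect_equal(ge_moment(2, d), num2, tolerance = 1e-4)
  expect_error(ge_moment(-1, ge_dist(1, 1)), "non-negative")
  # Cauchy-Schwarz ordering of the moment vector
  for (a in c(0.8, 1, 3, 7)) {
    d <- ge_dist(a, 2)
    expect_lt(ge_moment(1, d)^2, ge_moment(0, d) * ge_moment(2, d))
  }
})

test_that("rge sampling follows the GE law", {
  set.seed(42)
  d <- ge_dist(3, 2)
  x <- rge(2e4, d)
  expect_gt(stats::ks.test(x, function(q) ge_cdf(q, d))$p.value, 0.01)
  expect_equal(mean(x), ge_moment(1, d), tolerance = 0.02)
})

test_that("waiting-time fits recover generating parameters", {
  set.seed(7)
  # exponential data: GE fit returns shape ~ 1
  x <- rexp(1e4, rate = 1)
  f <- fit_waiting_time(x, family = "ge")
  expect_equal(unname(f$params["shape"]), 1, tolerance = 0.05)
  expect_equal(unname(f$params["rate"]), 1, tolerance = 0.05)
  # GE parameter recovery across the shape/scale box
  for (par in list(c(3, 2), c(1.5, 0.1), c(8, 40))) {
    x <- rge(1e4, ge_dist(par[1], par[2]))
    f <- fit_waiting_time(x, family = "ge")
    expect_lt(abs(f$params[["shape"]] - par[1]) / par[1], 0.1)
    expect_lt(abs(f$params[["rate"]] - par[2]) / par[2], 0.1)
  }
  # gamma and exponential families report their own parameters
  x <- rgamma(5000, shape = 2.5, rate = 4)
  fg <- fit_waiting_time(x, family = "gamma")
  expect_equal(unname(fg$params["shape"]), 2.5, tolerance = 0.1)
  fe <- fit_waiting_time(rexp(5000, 3), family = "exponential")
  expect_equal(unname(fe$params["rate"]), 3, tolerance = 0.1)
  expect_error(fit_waiting_time(rep(1, 100), "ge"), "degenerate")
  expect_error(fit_waiting_time(rexp(10), "ge"), "at least 50")
})

test_that("binned least-squares fits match the generating density", {
  d <- ge_dist(4, 6)
  t <- seq(0.02, 1.6, by = 0.04)
  bins <- data.frame(t = t, density = ge_pdf(t, d))
  f <- fit_waiting_time(bins, family = "ge")
  expect_equal(unname(f$params["shape"]), 4, tolerance = 1e-3)
  expect_equal(unname(f$params["rate"]), 6, tolerance = 1e-3)
  fg <- fit_waiting_time(data.frame(t = t, density = dgamma(t, 3, 8)),
                         family = "gamma")
  expect_equal(unname(fg$params["shape"]), 3, tolerance = 1e-3)
  expect_error(fit_waiting_time(data.frame(t = 1:5, density = rep(1, 5)), "ge"),
               "10 positive")
})
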