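test_that("power-law fit is exact on noiseless A*t^b data", {
  t <- seq(0.1, 100, by = 0.1)
  fit <- fit_power_law(t, 2 * t^0.5)
  expect_equal(fit$A, 2, tolerance = 1e-12)
  expect_equal(fit$b, 0.5, tolerance = 1e-12)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-10)
})

test_that("power-law exponent is recovered within 0.02 under 1% noise", {
  set.seed(17)
  t <- seq(0.1, 100, length.out = 1000)
  sigma <- 3 * t^0.7 * exp(rnorm(1000, sd = 0.01))
  fit <- fit_power_law(t, sigma)
  expect_lt(abs(fit$b - 0.7), 0.02)
  expect_equal(fit$A, 3, tolerance = 0.05)
})

test_that("power-law fit rejects degenerate sigma and short ranges", {
  t <- seq(0.1, 10, by = 0.1)
  expect_error(fit_power_law(t, c(rep(1, 50), 0, rep(1, 49))), "sigma")
  expect_error(fit_power_law(t[1:5], (2 * t^0.5)[1:5]), "fewer than 10")
  # sigma shrinking with t has no positive exponent
  expect_error(fit_power_law(t, 2 * t^-0.5), "not positive")
})

test_that("triexponential fit recovers noiseless model curves to < 0.1%", {
  tt <- seq(0.01, 60, by = 0.01)
  cases <- list(
    list(B = 1, amps = c(0.5, 0.3, 0.2), taus = c(0.1, 1, 10)),
    list(B = 0.04, amps = c(0.2, 0.5, 0.3), taus = c(0.5, 3, 15)),
    list(B = 12, amps = c(0.6, 0.3, 0.1), taus = c(0.05, 0.8, 7))
  )
  for (cs in cases) {
    y <- multiexp_curve(tt, cs$B, cs$amps, cs$taus)
    eta_true <- cs$B * sum(cs$amps * cs$taus)
    for (seed in c(1, 2)) {
      fit <- fit_multiexponential(tt, y, b = 0.5, seed = seed)
      expect_lt(abs(fit$eta_infinity - eta_true) / eta_true, 1e-3)
      expect_true(fit$converged)
      expect_true(all(diff(fit$tau) >= 0))
    }
  }
})

test_that("degenerate single-exponential input yields eta_infinity = B*tau1", {
  tt <- seq(0.01, 50, by = 0.01)
  y <- multiexp_curve(tt, 2, 1, 3) # single saturating exponential, B*tau = 6
  fit <- fit_multiexponential(tt, y, b = 0.5)
  expect_equal(fit$eta_infinity, 6, tolerance = 1e-3)
  bi <- fit_multiexponential(tt, y, b = 0.5, form = "biexponential")
  expect_equal(bi$eta_infinity, 6, tolerance = 1e-3)
})

test_that("rescaling sigma changes A but not b; weights are scale-free", {
  set.seed(23)
  t <- seq(0.1, 50, length.out = 500)
  sigma <- 2 * t^0.6 * exp(rnorm(500, sd = 0.02))
  f1 <- fit_power_law(t, sigma)
  f2 <- fit_power_law(t, 7 * sigma)
  expect_equal(f2$b, f1$b, tolerance = 1e-12)
  expect_equal(f2$A, 7 * f1$A, tolerance = 1e-9)

  # the weighted fit depends on b only through relative weights, so the same
  # curve fitted with the two power laws gives the same viscosity
  tt <- seq(0.01, 60, by = 0.01)
  y <- multiexp_curve(tt, 1, c(0.5, 0.3, 0.2), c(0.1, 1, 10))
  e1 <- fit_multiexponential(tt, y, b = f1$b)$eta_infinity
  e2 <- fit_multiexponential(tt, y, b = f2$b)$eta_infinity
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("triexponential weighted residual is <= biexponential on slow-rise curves", {
  tt <- seq(0.01, 80, by = 0.01)
  # three well-separated timescales produce the slow rise a biexponential
  # cannot capture
  y <- multiexp_curve(tt, 0.5, c(0.6, 0.25, 0.15), c(0.05, 2, 40))
  tri <- fit_multiexponential(tt, y, b = 0.6, form = "triexponential")
  bi <- fit_multiexponential(tt, y, b = 0.6, form = "biexponential")
  expect_lte(tri$residual_norm, bi$residual_norm * (1 + 1e-6))
  expect_gt(bi$residual_norm, 10 * tri$residual_norm) # clearly distinguishable
})

test_that("aggregate_sets reproduces the between-set uncertainty convention", {
  est <- aggregate_sets(c(7.5, 14.4, 7.2), 9.2)
  expect_equal(round(est$uncertainty, 1), 5.8)
  est2 <- aggregate_sets(c(31.2, 20.3, 24.4), 24.1)
  expect_equal(round(est2$uncertainty, 1), 7.8)
  # the plain sample sd is exposed as the alternative convention
  expect_equal(est$uncertainty_sd, sd(c(7.5, 14.4, 7.2)))
  expect_equal(est$uncertainty, sd(c(7.5, 14.4, 7.2)) * sqrt(2))

  same <- aggregate_sets(c(5, 5, 5), 5)
  expect_equal(same$uncertainty, 0)

  # permutation invariance
  p1 <- aggregate_sets(c(7.5, 14.4, 7.2), 9.2)$uncertainty
  p2 <- aggregate_sets(c(14.4, 7.2, 7.5), 9.2)$uncertainty
  expect_equal(p1, p2)

  expect_error(aggregate_sets(7.5, 9.2), "at least 2")
})

test_that("aggregate_sets accepts fitted objects and numeric vectors alike", {
  tt <- seq(0.01, 30, by = 0.01)
  fits <- lapply(c(1, 1.2, 0.9), function(s) {
    fit_multiexponential(tt, multiexp_curve(tt, s, c(0.5, 0.3, 0.2), c(0.1, 1, 5)),
      b = 0.5, restarts = 8
    )
  })
  est <- aggregate_sets(fits, fits[[1]])
  expect_equal(est$n_sets, 3)
  expect_equal(est$combined_eta, fits[[1]]$eta_infinity)
  expect_equal(
    est$set_etas,
    vapply(fits, function(f) f$eta_infinity, numeric(1))
  )
})

test_that("truncation agrees when tau_max is far inside the window, biases low otherwise", {
  tt <- seq(0.01, 100, by = 0.01)
  # information-complete truncation: tau_max = 2 << 20
  y_fast <- multiexp_curve(tt, 1, c(0.5, 0.3, 0.2), c(0.05, 0.5, 2))
  full <- fit_multiexponential(tt, y_fast, b = 0.5)
  trunc <- truncation_check(tt, y_fast, b = 0.5, truncated_range = c(0.01, 20))
  expect_equal(trunc$eta_infinity, full$eta_infinity, tolerance = 1e-3)

  # tau_max comparable to (here: beyond) the truncation window: the slow
  # rise cannot be pinned down from the window, and the truncated estimate
  # is biased low
  y_slow <- multiexp_curve(tt, 1, c(0.4, 0.3, 0.3), c(0.1, 2, 60))
  eta_true <- 1 * sum(c(0.4, 0.3, 0.3) * c(0.1, 2, 60))
  tr2 <- truncation_check(tt, y_slow, b = 0.5, truncated_range = c(0.01, 20))
  expect_lt(tr2$eta_infinity, eta_true)
  full2 <- fit_multiexponential(tt, y_slow, b = 0.5)
  expect_equal(full2$eta_infinity, eta_true, tolerance = 1e-3)

  expect_error(
    truncation_check(tt, y_fast, b = 0.5, truncated_range = c(0.01, 100)),
    "before the full range"
  )
})
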