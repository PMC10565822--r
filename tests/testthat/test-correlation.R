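test_that("combine_components forms off-diagonal and diagonal-difference channels", {
  n <- 20
  s <- pressure_series(
    components = list(
      xx = rep(3, n), yy = rep(1, n), zz = rep(2, n),
      xy = rnorm(n), xz = rnorm(n), yz = rnorm(n)
    ),
    time_step = 0.1, volume = 100, temperature = 298
  )
  cs <- combine_components(s)
  expect_named(cs$channels, c("xy", "xz", "yz", "xx-yy", "xx-zz", "yy-zz"))
  expect_equal(cs$channels[["xx-yy"]], rep(1.0, n))
  expect_equal(cs$channels[["xx-zz"]], rep(0.5, n))
  expect_equal(cs$channels[["yy-zz"]], rep(-0.5, n))
})

test_that("isotropic diagonals give identically zero difference channels", {
  n <- 10
  d <- rnorm(n)
  s <- pressure_series(
    components = list(
      xx = d, yy = d, zz = d,
      xy = rnorm(n), xz = rnorm(n), yz = rnorm(n)
    ),
    time_step = 0.1, volume = 100, temperature = 298
  )
  cs <- combine_components(s)
  expect_equal(cs$channels[["xx-yy"]], rep(0, n))
  expect_equal(cs$channels[["xx-zz"]], rep(0, n))
  expect_equal(cs$channels[["yy-zz"]], rep(0, n))
})

test_that("transpose pairs are averaged elementwise; equal pairs are the identity", {
  n <- 15
  v <- rnorm(n)
  w <- rnorm(n)
  s <- pressure_series(
    components = list(xy = v, yx = v, xz = v, zx = w, yz = rnorm(n)),
    time_step = 0.1, volume = 100, temperature = 298
  )
  cs <- combine_components(s)
  expect_equal(cs$channels$xy, v) # identical pair -> identity
  expect_equal(cs$channels$xz, (v + w) / 2) # distinct pair -> mean
  expect_equal(length(cs$channels), 3) # no diagonals supplied -> 3 channels
})

test_that("compute_acf matches closed forms on constant and alternating input", {
  a <- compute_acf(rep(2, 8), time_step = 1)
  expect_equal(a$values, rep(4, 8))
  expect_equal(a$lags, 0:7)

  b <- compute_acf(c(1, -1, 1, -1), time_step = 1)
  expect_equal(b$values, c(1, -1, 1, -1))
})

test_that("FFT ACF equals the direct O(N^2) oracle on random input", {
  set.seed(101)
  for (n in c(2, 3, 17, 256, 1024)) {
    x <- rnorm(n)
    for (est in c("unbiased", "biased")) {
      got <- compute_acf(x, time_step = 1, estimator = est)$values
      want <- acf_direct(x, n, estimator = est)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("ACF(0) is the mean of squares under both estimators", {
  set.seed(5)
  x <- rnorm(500)
  expect_equal(compute_acf(x, 1, estimator = "unbiased")$values[1], mean(x^2))
  expect_equal(compute_acf(x, 1, estimator = "biased")$values[1], mean(x^2))
})

test_that("compute_acf validates max_lag and input length", {
  expect_error(compute_acf(rnorm(10), 1, max_lag = 10), "max_lag")
  expect_error(compute_acf(numeric(1), 1), "length")
  # max_lag truncation yields floor(max_lag/dt)+1 lags
  a <- compute_acf(rnorm(100), 0.5, max_lag = 7.5)
  expect_equal(length(a$lags), 16)
  expect_equal(a$lags[16], 7.5)
})

test_that("mean subtraction is off by default and available as a flag", {
  x <- rnorm(200) + 5
  raw <- compute_acf(x, 1)$values[1]
  cen <- compute_acf(x, 1, subtract_mean = TRUE)$values[1]
  expect_equal(raw, mean(x^2))
  expect_equal(cen, mean((x - mean(x))^2))
})

test_that("average_acfs is idempotent on identical sets and even under sign flip", {
  set.seed(7)
  s <- make_series(rnorm(64), rnorm(64), rnorm(64))
  cs <- combine_components(s)
  one <- average_acfs(list(cs))
  two <- average_acfs(list(cs, cs))
  expect_equal(two$values, one$values)
  expect_equal(two$n_trajectories, 2)
  expect_equal(two$n_channels, 6)

  neg <- cs
  neg$channels <- lapply(cs$channels, function(v) -v)
  both <- average_acfs(list(cs, neg))
  expect_equal(both$values, one$values)
})

test_that("combined ensemble ACF equals the mean of equal-size set ACFs", {
  set.seed(13)
  sets <- replicate(3, {
    lapply(1:7, function(i) combine_components(make_series(rnorm(50), rnorm(50), rnorm(50))))
  }, simplify = FALSE)
  per_set <- lapply(sets, average_acfs)
  all21 <- average_acfs(unlist(sets, recursive = FALSE))
  mean_of_sets <- Reduce(`+`, lapply(per_set, `[[`, "values")) / 3
  expect_equal(all21$values, mean_of_sets, tolerance = 1e-12)
})

test_that("average_acfs rejects mixed time steps and empty input", {
  a <- combine_components(make_series(rnorm(10), dt = 0.1))
  b <- combine_components(make_series(rnorm(10), dt = 0.2))
  expect_error(average_acfs(list(a, b)), "mixed time steps")
  expect_error(average_acfs(list()), "empty")
})

test_that("averaged unbiased ACF of white noise is zero within 5 standard errors", {
  set.seed(31)
  s2 <- 1.7 # noise variance
  M <- 60
  N <- 2000
  sets <- lapply(seq_len(M / 3), function(i) {
    make_series(
      rnorm(N, sd = sqrt(s2)), rnorm(N, sd = sqrt(s2)), rnorm(N, sd = sqrt(s2))
    )
  })
  a <- average_acfs(lapply(sets, combine_components), max_lag = 50)
  for (k in c(1, 5, 25, 50)) {
    se <- s2 / sqrt(M * (N - k))
    expect_lt(abs(a$values[k + 1]), 5 * se)
  }
})
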