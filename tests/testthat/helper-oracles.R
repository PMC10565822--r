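# Independent oracles used across the suite. These deliberately use the
# slow, obvious computation so they stay independent of the package's
# fast-path implementations.

# Direct O(N^2) time-origin-averaged autocorrelation.
acf_direct <- function(x, n_lags, estimator = "unbiased") {
  n <- length(x)
  vapply(seq_len(n_lags) - 1L, function(k) {
    s <- sum(x[seq_len(n - k)] * x[seq_len(n - k) + k])
    s / if (estimator == "unbiased") (n - k) else n
  }, numeric(1))
}

# Saturating multi-exponential running-integral model, written out longhand.
multiexp_curve <- function(t, B, amps, taus) {
  y <- numeric(length(t))
  for (i in seq_along(taus)) {
    y <- y + amps[i] * taus[i] * (1 - exp(-t / taus[i]))
  }
  B * y
}

# Minimal valid pressure series with given off-diagonal channels.
make_series <- function(xy, xz = xy, yz = xy, dt = 0.1, volume = 100,
                        temperature = 298, ...) {
  pressure_series(
    components = list(xy = xy, xz = xz, yz = yz),
    time_step = dt, volume = volume, temperature = temperature, ...
  )
}

# Constant-value gk_curve on a given grid (for ensemble statistics tests).
make_const_curve <- function(times, value, source = "c") {
  structure(
    list(
      times = times, eta = rep(value, length(times)), volume = 100,
      temperature = 298, source = source
    ),
    class = "gk_curve"
  )
}
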