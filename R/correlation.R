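#' Form the statistically exploitable pressure channels
#'
#' In an isotropic fluid the Green-Kubo integrand may be averaged over the
#' three off-diagonal pressure-tensor elements. When the diagonal elements
#' are also available, three additional channels with the same
#' autocorrelation statistics are formed from pairwise differences,
#' improving statistics at no extra simulation cost:
#' `(Pxx - Pyy)/2`, `(Pxx - Pzz)/2` and `(Pyy - Pzz)/2`.
#'
#' Off-diagonal channels are replaced by the elementwise mean with their
#' transpose when the transpose is present (the pressure tensor is symmetric
#' up to constraint noise, so `(Pxy + Pyx)/2` is the better estimate of the
#' shear stress).
#'
#' @param series a [pressure_series()] with at least the off-diagonal
#'   components (or their transposes).
#' @return an object of class `channel_set`: list with `channels` (named list
#'   of numeric vectors \[bar\]), `time_step` \[ps\], and `source`
#'   (trajectory id).
#' @export
#' @examples
#' ps <- pressure_series(
#'   components = list(
#'     xx = rnorm(50), yy = rnorm(50), zz = rnorm(50),
#'     xy = rnorm(50), xz = rnorm(50), yz = rnorm(50)
#'   ),
#'   time_step = 0.004, volume = 1000, temperature = 298
#' )
#' names(combine_components(ps)$channels)
combine_components <- function(series) {
  validate_pressure_series(series)
  comps <- series$components
  chans <- list()
  for (lab in c("xy", "xz", "yz")) {
    tlab <- .transpose_of[[lab]]
    if (lab %in% names(comps) && tlab %in% names(comps)) {
      chans[[lab]] <- (comps[[lab]] + comps[[tlab]]) / 2
    } else if (lab %in% names(comps)) {
      chans[[lab]] <- comps[[lab]]
    } else if (tlab %in% names(comps)) {
      chans[[lab]] <- comps[[tlab]]
    } else {
      stop("combine_components: missing off-diagonal component ", lab)
    }
  }
  if (all(c("xx", "yy", "zz") %in% names(comps))) {
    chans[["xx-yy"]] <- (comps$xx - comps$yy) / 2
    chans[["xx-zz"]] <- (comps$xx - comps$zz) / 2
    chans[["yy-zz"]] <- (comps$yy - comps$zz) / 2
  }
  structure(
    list(
      channels = chans, time_step = series$time_step,
      source = series$trajectory_id, set_id = series$set_id
    ),
    class = "channel_set"
  )
}

.fast_len <- function(n) {
  # smallest highly-composite FFT length >= n (powers of 2, 3, 5)
  stats::nextn(n, factors = c(2, 3, 5))
}

#' Time-origin-averaged autocorrelation function
#'
#' Computes `ACF[k] = sum_i x[i] * x[i+k] / D_k` over all available time
#' origins, with `D_k = N - k` (unbiased, the default) or `D_k = N`
#' (biased). The sum is evaluated by zero-padded FFT (Wiener-Khinchin),
#' which equals the direct sum to floating-point accuracy. No mean is
#' subtracted by default: shear-stress channels average to zero in an
#' isotropic fluid, and subtracting a noisy sample mean biases the long-lag
#' tail.
#'
#' @param x numeric sequence (one pressure channel) \[bar\].
#' @param time_step sampling interval \[ps\].
#' @param max_lag largest lag \[ps\]; default the full series span
#'   `(length(x) - 1) * time_step`.
#' @param estimator `"unbiased"` (divide by `N - k`) or `"biased"` (by `N`).
#' @param subtract_mean subtract the sample mean first (diagnostic use).
#' @return list with `lags` \[ps\] (uniform grid from 0) and `values`
#'   \[bar^2\].
#' @export
compute_acf <- function(x, time_step, max_lag = NULL,
                        estimator = c("unbiased", "biased"),
                        subtract_mean = FALSE) {
  estimator <- match.arg(estimator)
  n <- length(x)
  if (n < 2) stop("compute_acf: sequence length must be >= 2")
  if (!is.numeric(time_step) || time_step <= 0) {
    stop("compute_acf: time_step must be positive")
  }
  if (is.null(max_lag)) max_lag <- (n - 1) * time_step
  n_lags <- floor(max_lag / time_step + 1e-9) + 1L
  if (n_lags > n) {
    stop(
      "compute_acf: max_lag (", max_lag, " ps) must be < series span (",
      (n - 1) * time_step, " ps)"
    )
  }
  if (subtract_mean) x <- x - mean(x)
  nf <- .fast_len(n + n_lags)
  xp <- c(x, numeric(nf - n))
  s <- Re(stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE))[seq_len(n_lags)] / nf
  denom <- if (estimator == "unbiased") n - (seq_len(n_lags) - 1L) else rep(n, n_lags)
  list(lags = time_step * (seq_len(n_lags) - 1L), values = s / denom)
}

#' Average autocorrelation functions over channels and trajectories
#'
#' Computes the ACF of every channel of every supplied channel set and takes
#' the unweighted arithmetic mean, recording provenance counts. All channel
#' sets must share one time step. Per-set averages are obtained by calling
#' this function on the subsets of a partition.
#'
#' @param channel_sets list of [combine_components()] results.
#' @param max_lag largest lag \[ps\]; default the full common span.
#' @param estimator passed to [compute_acf()].
#' @param subtract_mean passed to [compute_acf()].
#' @return an object of class `ensemble_acf`: `lags` \[ps\], `values`
#'   \[bar^2\], `n_channels`, `n_trajectories`, `max_lag`, `time_step`.
#' @export
average_acfs <- function(channel_sets, max_lag = NULL,
                         estimator = c("unbiased", "biased"),
                         subtract_mean = FALSE) {
  estimator <- match.arg(estimator)
  if (length(channel_sets) == 0) stop("average_acfs: empty input")
  stopifnot(all(vapply(channel_sets, inherits, logical(1), "channel_set")))
  dts <- vapply(channel_sets, function(cs) cs$time_step, numeric(1))
  if (max(dts) - min(dts) > 1e-9 * dts[1]) {
    stop("average_acfs: mixed time steps across channel sets")
  }
  acc <- NULL
  lags <- NULL
  n_ch <- 0L
  for (cs in channel_sets) {
    for (ch in cs$channels) {
      a <- compute_acf(ch, cs$time_step,
        max_lag = max_lag, estimator = estimator,
        subtract_mean = subtract_mean
      )
      if (is.null(acc)) {
        acc <- a$values
        lags <- a$lags
      } else {
        if (length(a$values) != length(acc)) {
          stop("average_acfs: channel lengths yield differing lag grids")
        }
        acc <- acc + a$values
      }
      n_ch <- n_ch + 1L
    }
  }
  structure(
    list(
      lags = lags, values = acc / n_ch, n_channels = n_ch,
      n_trajectories = length(channel_sets),
      max_lag = lags[length(lags)], time_step = dts[1]
    ),
    class = "ensemble_acf"
  )
}

#' @export
print.ensemble_acf <- function(x, ...) {
  cat(
    "Ensemble ACF: ", length(x$lags), " lags (0 .. ",
    format(x$max_lag, big.mark = ","), " ps), averaged over ",
    x$n_channels, " channels from ", x$n_trajectories, " trajectories\n",
    sep = ""
  )
  cat("  ACF(0) =", signif(x$values[1], 6), "bar^2\n")
  invisible(x)
}
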