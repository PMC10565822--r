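#' Green-Kubo unit conversion factor
#'
#' The Green-Kubo relation gives the shear viscosity as
#' `eta = V / (kB * T) * integral ACF(t) dt`. With the package's I/O units
#' (ACF in bar^2, time in ps, volume in nm^3) the prefactor in SI is
#' `V * 1e-29 / (kB * T)` Pa.s per bar^2.ps
#' (1 bar = 1e5 Pa, 1 ps = 1e-12 s, 1 nm^3 = 1e-27 m^3), returned here
#' scaled to mPa.s. `kB = 1.380649e-23` J/K exactly.
#'
#' @param volume box volume \[nm^3\], > 0.
#' @param temperature temperature \[K\], > 0.
#' @return multiplier \[mPa.s per bar^2.ps\].
#' @export
#' @examples
#' unit_factor(100, 298) # 2.431e-4 mPa.s per bar^2.ps
unit_factor <- function(volume, temperature) {
  kB <- 1.380649e-23
  if (!is.numeric(volume) || volume <= 0) stop("unit_factor: volume must be > 0")
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("unit_factor: temperature must be > 0")
  }
  volume * 1e-29 / (kB * temperature) * 1e3
}

#' Running Green-Kubo viscosity integral
#'
#' Cumulative trapezoidal integral of a pressure autocorrelation function
#' over lag time, multiplied by [unit_factor()]. The running integral
#' `eta(t)` starts at 0 and plateaus at the shear viscosity once the ACF has
#' decayed; on noisy data the plateau is extracted by the time-decomposition
#' fit ([fit_multiexponential()]) rather than read off directly.
#'
#' @param acf an `ensemble_acf` from [average_acfs()], or a list with
#'   uniform `lags` \[ps\] and `values` \[bar^2\].
#' @param volume box volume \[nm^3\].
#' @param temperature temperature \[K\].
#' @param source label for the curve (trajectory id or `"ensemble"`).
#' @return object of class `gk_curve`: `times` \[ps\], `eta` \[mPa.s\],
#'   `volume`, `temperature`, `source`.
#' @export
running_integral <- function(acf, volume, temperature, source = "ensemble") {
  lags <- acf$lags
  vals <- acf$values
  if (length(lags) < 2) stop("running_integral: need at least 2 lags")
  dl <- diff(lags)
  if (any(dl <= 0) || max(dl) - min(dl) > 1e-9 * dl[1]) {
    stop("running_integral: non-uniform lag grid")
  }
  dt <- dl[1]
  fac <- unit_factor(volume, temperature)
  eta <- fac * dt * c(0, cumsum((vals[-length(vals)] + vals[-1]) / 2))
  structure(
    list(
      times = lags, eta = eta, volume = volume,
      temperature = temperature, source = source
    ),
    class = "gk_curve"
  )
}

#' Assemble per-trajectory running integrals into an ensemble
#'
#' Stacks N per-trajectory running viscosity curves on a common time grid
#' and computes the pointwise ensemble mean `<eta(t)>`, the pointwise
#' standard deviation `sigma(t)` (sample, N-1 divisor), and per-set mean
#' curves for a partition of the trajectories into repeat sets. `sigma(t)`
#' feeds the power-law stage of the time-decomposition fit; the per-set
#' means provide the conservative between-set uncertainty estimate.
#'
#' @param curves list of [running_integral()] results sharing one time grid.
#' @param sets optional named list of index vectors partitioning the curves
#'   into repeat sets (e.g. 3 sets of 21).
#' @return object of class `gk_ensemble`: `times`, `eta_mat` (time x N
#'   matrix), `mean_curve`, `sigma_curve`, `set_means` (named list), `n`,
#'   `sources`, `volume`, `temperature`.
#' @export
build_ensemble <- function(curves, sets = NULL) {
  n <- length(curves)
  if (n < 1) stop("build_ensemble: need at least 1 curve")
  stopifnot(all(vapply(curves, inherits, logical(1), "gk_curve")))
  times <- curves[[1]]$times
  for (cv in curves) {
    if (length(cv$times) != length(times) ||
      max(abs(cv$times - times)) > 1e-9 * (times[2] - times[1])) {
      stop("build_ensemble: curves do not share one time grid")
    }
  }
  m <- vapply(curves, function(cv) cv$eta, numeric(length(times)))
  mean_curve <- rowMeans(m)
  # sigma(t) exists only for N >= 2 (sample, N-1 divisor)
  sigma_curve <- if (n >= 2) {
    sqrt(rowSums((m - mean_curve)^2) / (n - 1))
  } else {
    rep(NA_real_, length(times))
  }
  set_means <- NULL
  if (!is.null(sets)) {
    idx <- sort(unlist(sets, use.names = FALSE))
    if (!identical(as.integer(idx), seq_len(n))) {
      stop("build_ensemble: sets must disjointly cover all curves")
    }
    set_means <- lapply(sets, function(ii) rowMeans(m[, ii, drop = FALSE]))
  }
  structure(
    list(
      times = times, eta_mat = m, mean_curve = mean_curve,
      sigma_curve = sigma_curve, set_means = set_means, n = n,
      sources = vapply(curves, function(cv) cv$source, character(1)),
      volume = curves[[1]]$volume, temperature = curves[[1]]$temperature
    ),
    class = "gk_ensemble"
  )
}

#' @export
print.gk_ensemble <- function(x, ...) {
  cat(
    "Running-viscosity ensemble: N = ", x$n, " trajectories, ",
    length(x$times), " time points (0 .. ",
    format(x$times[length(x$times)], big.mark = ","), " ps)\n",
    sep = ""
  )
  if (!is.null(x$set_means)) {
    cat("  sets:", paste(names(x$set_means), collapse = ", "), "\n")
  }
  cat(
    "  <eta> at final time:", signif(x$mean_curve[length(x$mean_curve)], 4),
    "mPa.s (plateau should be taken from the fit, not this value)\n"
  )
  invisible(x)
}

#' Plot a running-viscosity ensemble
#'
#' Per-trajectory curves in grey, ensemble mean in black, per-set means (if
#' present) as coloured lines; optionally overlays a fitted curve.
#'
#' @param x a `gk_ensemble`.
#' @param fit optional `multiexp_fit` to overlay.
#' @param max_curves cap on the number of per-trajectory curves drawn.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.gk_ensemble <- function(x, fit = NULL, max_curves = 63, ...) {
  sel <- seq_len(min(ncol(x$eta_mat), max_curves))
  graphics::matplot(x$times, x$eta_mat[, sel],
    type = "l", lty = 1,
    col = grDevices::grey(0.8), xlab = "t [ps]",
    ylab = expression(eta(t) ~ "[mPa s]"), ...
  )
  graphics::lines(x$times, x$mean_curve, lwd = 2)
  if (!is.null(x$set_means)) {
    for (i in seq_along(x$set_means)) {
      graphics::lines(x$times, x$set_means[[i]], col = i + 1)
    }
  }
  if (!is.null(fit)) {
    graphics::lines(x$times, predict(fit, x$times), col = "red", lty = 2, lwd = 2)
  }
  invisible(x)
}
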