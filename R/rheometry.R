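#' Cone-plate torque-to-viscosity conversion
#'
#' For a shallow cone of angle `alpha` rotating at angular velocity `omega`
#' above a plate, the shear rate `omega / alpha` is uniform across the gap
#' and the shear stress is `3 M / (2 pi R^3)`, so the dynamic viscosity is
#' `eta = 3 M alpha / (2 pi R^3 omega)`. Valid in the small-angle regime
#' (alpha up to a few degrees).
#'
#' @param torque M \[N.m\].
#' @param angular_velocity omega \[rad/s\], > 0.
#' @param cone_angle alpha \[rad\], in (0, 0.1].
#' @param cone_radius R \[m\], > 0.
#' @return viscosity \[mPa.s\].
#' @export
#' @examples
#' # 10 Pa shear stress at shear rate ~3283 1/s -> ~3 mPa.s
#' R <- 17.5e-3; a <- pi / 180
#' M <- 10 * 2 * pi * R^3 / 3
#' cone_plate_viscosity(M, 57.3, a, R)
cone_plate_viscosity <- function(torque, angular_velocity, cone_angle,
                                 cone_radius) {
  if (any(angular_velocity <= 0)) {
    stop("cone_plate_viscosity: angular_velocity must be > 0")
  }
  if (any(cone_radius <= 0)) stop("cone_plate_viscosity: cone_radius must be > 0")
  if (any(cone_angle <= 0) || any(cone_angle > 0.1)) {
    stop("cone_plate_viscosity: cone_angle must be in (0, 0.1] rad (small-angle regime)")
  }
  3 * torque * cone_angle / (2 * pi * cone_radius^3 * angular_velocity) * 1e3
}

#' Rheometry dataset of (concentration, viscosity) pairs
#'
#' @param concentration mass concentrations \[mg/mL\], >= 0.
#' @param viscosity dynamic viscosities \[mPa.s\], > 0.
#' @param filtered logical flags (sample sterile-filtered or not).
#' @param temperature measurement temperature \[K\].
#' @return object of class `rheo_dataset` (also a data.frame with columns
#'   `concentration`, `viscosity`, `filtered`).
#' @export
rheo_dataset <- function(concentration, viscosity,
                         filtered = rep(TRUE, length(concentration)),
                         temperature = 297) {
  stopifnot(
    length(concentration) == length(viscosity),
    length(filtered) == length(concentration),
    all(concentration >= 0), all(viscosity > 0)
  )
  df <- data.frame(
    concentration = concentration, viscosity = viscosity,
    filtered = as.logical(filtered)
  )
  structure(df,
    temperature = temperature,
    class = c("rheo_dataset", "data.frame")
  )
}

#' Read a rheometry table from delimited text
#'
#' Expects columns `concentration` \[mg/mL\], `viscosity` \[mPa.s\] and
#' optionally `filtered` (logical); delimiter auto-detected among comma,
#' tab and whitespace; `#` lines are comments. A measured mAb solution
#' dataset at 297 K ships with the package:
#' `system.file("extdata", "mab_rheometry_297K.tsv", package = "gkvisc")`.
#'
#' @param path file to read.
#' @param temperature measurement temperature \[K\].
#' @return a [rheo_dataset()].
#' @export
read_rheo_table <- function(path, temperature = 297) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  df <- utils::read.table(path,
    header = TRUE, comment.char = "#",
    sep = "", stringsAsFactors = FALSE
  )
  if (ncol(df) == 1 && grepl(",", readLines(path, n = 2)[2])) {
    df <- utils::read.table(path,
      header = TRUE, comment.char = "#", sep = ",",
      stringsAsFactors = FALSE
    )
  }
  need <- c("concentration", "viscosity")
  if (!all(need %in% names(df))) {
    stop("'", path, "' must have columns: ", paste(need, collapse = ", "))
  }
  filt <- if ("filtered" %in% names(df)) as.logical(df$filtered) else rep(TRUE, nrow(df))
  rheo_dataset(df$concentration, df$viscosity, filt, temperature)
}

.rm_log_eta <- function(rho, log_eta0, ieta, ratio) {
  d <- 1 - ratio * ieta * rho
  ifelse(d > 0, log_eta0 + ieta * rho / d, Inf)
}

#' Evaluate a Ross-Minton concentration-viscosity curve
#'
#' `eta(rho) = eta0 * exp([eta] * rho / (1 - (k/v) * [eta] * rho))`, where
#' `eta0` is the buffer viscosity, `[eta]` the intrinsic viscosity of the
#' solute, `k` a crowding factor and `v` a shape parameter. Only the ratio
#' `k/v` is identifiable, so a single `crowding_ratio` parameter is used.
#' The curve is strictly increasing and log-convex on its domain
#' `rho < 1 / (crowding_ratio * [eta])`.
#'
#' @param fit a `ross_minton_fit`, or a list with `eta0` \[mPa.s\],
#'   `intrinsic_viscosity` \[mL/mg\] and `crowding_ratio`.
#' @param rho concentrations \[mg/mL\] inside the valid domain.
#' @return viscosities \[mPa.s\].
#' @export
ross_minton_eval <- function(fit, rho) {
  d <- 1 - fit$crowding_ratio * fit$intrinsic_viscosity * rho
  if (any(d <= 0)) {
    stop(
      "ross_minton_eval: rho at/beyond the singularity ",
      signif(1 / (fit$crowding_ratio * fit$intrinsic_viscosity), 5), " mg/mL"
    )
  }
  fit$eta0 * exp(fit$intrinsic_viscosity * rho / d)
}

#' Fit the Ross-Minton equation to rheometry data
#'
#' Least squares in log-viscosity space (the model is exponential in its
#' argument, so log space equalises relative errors across the measured
#' range). Filtered and unfiltered points are combined by default; duplicate
#' concentrations are retained as independent observations. The buffer
#' viscosity `eta0` is either fitted within \[0.5, 2.0\] mPa.s (default) or
#' fixed to a supplied value.
#'
#' @param data a [rheo_dataset()] with >= 4 points.
#' @param eta0_mode `"fitted"` (default) or `"fixed"`.
#' @param eta0_value buffer viscosity \[mPa.s\] when `eta0_mode = "fixed"`.
#' @param eta0_bounds bounds for the fitted buffer viscosity \[mPa.s\].
#' @return object of class `ross_minton_fit`: `eta0` \[mPa.s\],
#'   `intrinsic_viscosity` \[mL/mg\], `crowding_ratio` (= k/v), `eta0_mode`,
#'   `residual_norm` (RMS of log residuals), `n_points`.
#' @export
ross_minton_fit <- function(data, eta0_mode = c("fitted", "fixed"),
                            eta0_value = NULL, eta0_bounds = c(0.5, 2.0)) {
  eta0_mode <- match.arg(eta0_mode)
  stopifnot(inherits(data, "rheo_dataset"))
  if (nrow(data) < 4) stop("ross_minton_fit: need at least 4 points")
  if (eta0_mode == "fixed" && is.null(eta0_value)) {
    stop("ross_minton_fit: eta0_value required when eta0_mode = 'fixed'")
  }
  rho <- data$concentration
  ly <- log(data$viscosity)
  lo <- eta0_bounds[1]
  hi <- eta0_bounds[2]

  # unconstrained parameters: eta0 via logistic into [lo, hi] (when fitted),
  # ieta and ratio via log
  decode <- function(p) {
    if (eta0_mode == "fitted") {
      e0 <- lo + (hi - lo) / (1 + exp(-p[1]))
      list(eta0 = e0, ieta = exp(p[2]), ratio = exp(p[3]))
    } else {
      list(eta0 = eta0_value, ieta = exp(p[1]), ratio = exp(p[2]))
    }
  }
  resid_fn <- function(p) {
    q <- decode(p)
    r <- ly - .rm_log_eta(rho, log(q$eta0), q$ieta, q$ratio)
    r[!is.finite(r)] <- 1e6 # singularity inside the data range
    r
  }
  # multi-start over plausible intrinsic viscosities (protein solutions:
  # ~3-30 mL/g) and crowding ratios
  best <- NULL
  for (ie0 in c(0.003, 0.006, 0.012, 0.024)) {
    for (r0 in c(0.1, 0.4, 0.8)) {
      p0 <- c(if (eta0_mode == "fitted") 0, log(ie0), log(r0))
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = p0, fn = resid_fn,
          control = minpack.lm::nls.lm.control(
            maxiter = 500, ftol = 1e-14, ptol = 1e-14
          )
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || !all(is.finite(fit$par))) next
      rss <- sum(resid_fn(fit$par)^2)
      if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best)) stop("ross_minton_fit: no start converged")
  q <- decode(best$par)
  structure(
    list(
      eta0 = q$eta0, intrinsic_viscosity = q$ieta, crowding_ratio = q$ratio,
      eta0_mode = eta0_mode,
      residual_norm = sqrt(best$rss / length(rho)), n_points = length(rho)
    ),
    class = "ross_minton_fit"
  )
}

#' @export
print.ross_minton_fit <- function(x, ...) {
  cat("Ross-Minton fit (log-space least squares):\n")
  cat(
    "  eta0 =", signif(x$eta0, 4), "mPa.s (", x$eta0_mode, "),",
    " [eta] =", signif(x$intrinsic_viscosity, 4), "mL/mg,",
    " k/v =", signif(x$crowding_ratio, 4), "\n"
  )
  cat(
    "  singularity at rho =",
    signif(1 / (x$crowding_ratio * x$intrinsic_viscosity), 4), "mg/mL,",
    " rms log-residual =", signif(x$residual_norm, 3), "\n"
  )
  invisible(x)
}

#' Invert a Ross-Minton curve: concentration at a given viscosity
#'
#' Finds the unique `rho` with `ross_minton_eval(fit, rho) = eta`. The curve
#' is strictly increasing on its domain, so the root is bracketed and found
#' by [stats::uniroot()] (default); the closed-form inversion
#' `rho = L / ([eta] * (1 + (k/v) * L))` with `L = log(eta / eta0)` is
#' available as `method = "closed_form"`.
#'
#' @param fit a `ross_minton_fit`.
#' @param eta viscosity \[mPa.s\], > `fit$eta0`.
#' @param method `"bracket"` (monotone root bracketing, default) or
#'   `"closed_form"`.
#' @return concentration \[mg/mL\].
#' @export
invert_concentration <- function(fit, eta, method = c("bracket", "closed_form")) {
  method <- match.arg(method)
  if (any(eta <= fit$eta0)) {
    stop(
      "invert_concentration: eta must exceed the buffer viscosity eta0 = ",
      signif(fit$eta0, 4), " mPa.s"
    )
  }
  L <- log(eta / fit$eta0)
  closed <- L / (fit$intrinsic_viscosity * (1 + fit$crowding_ratio * L))
  if (method == "closed_form") {
    return(closed)
  }
  rho_max <- 1 / (fit$crowding_ratio * fit$intrinsic_viscosity)
  vapply(seq_along(L), function(i) {
    upper <- if (is.finite(rho_max)) rho_max * (1 - 1e-12) else 2 * closed[i] + 1
    stats::uniroot(
      function(r) {
        .rm_log_eta(r, log(fit$eta0), fit$intrinsic_viscosity, fit$crowding_ratio) -
          (log(fit$eta0) + L[i])
      },
      lower = 0, upper = upper,
      tol = 1e-12 * max(closed[i], 1)
    )$root
  }, numeric(1))
}

#' Concentration-uncertainty band for a Ross-Minton fit
#'
#' Sample concentrations of highly concentrated protein solutions are
#' typically uncertain at the ~10% level. The band is formed from two
#' additional fits, one with all concentrations scaled by `(1 - u)` and one
#' by `(1 + u)`; the envelope of the two fitted curves brackets the central
#' fit at every concentration.
#'
#' @param data a [rheo_dataset()].
#' @param relative_uncertainty u, in (0, 0.5).
#' @param ... passed to [ross_minton_fit()].
#' @return list with `central`, `lower`, `upper` (all `ross_minton_fit`;
#'   `lower`/`upper` by curve position: the fit to `(1+u)`-scaled
#'   concentrations lies below the central curve) and `band(rho)`, a
#'   function returning a 2-column matrix of envelope bounds.
#' @export
concentration_uncertainty_band <- function(data, relative_uncertainty = 0.10,
                                           ...) {
  u <- relative_uncertainty
  if (u < 0 || u >= 0.5) {
    stop("concentration_uncertainty_band: relative_uncertainty must be in [0, 0.5)")
  }
  central <- ross_minton_fit(data, ...)
  scale_fit <- function(s) {
    d <- rheo_dataset(
      data$concentration * s, data$viscosity, data$filtered,
      attr(data, "temperature")
    )
    ross_minton_fit(d, ...)
  }
  up_scaled <- scale_fit(1 + u) # same eta at higher recorded rho -> lower curve
  down_scaled <- scale_fit(1 - u) # -> upper curve
  band <- function(rho) {
    lo <- ross_minton_eval(up_scaled, rho)
    hi <- ross_minton_eval(down_scaled, rho)
    cbind(lower = pmin(lo, hi), upper = pmax(lo, hi))
  }
  list(central = central, lower = up_scaled, upper = down_scaled, band = band)
}

#' Plot a Ross-Minton fit with data and optional uncertainty band
#'
#' @param x a `ross_minton_fit`.
#' @param data optional [rheo_dataset()] of measured points.
#' @param band optional result of [concentration_uncertainty_band()].
#' @param rho_max largest concentration to draw \[mg/mL\].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ross_minton_fit <- function(x, data = NULL, band = NULL,
                                 rho_max = NULL, ...) {
  if (is.null(rho_max)) {
    rho_max <- if (!is.null(data)) 1.15 * max(data$concentration) else 250
  }
  rho <- seq(0, rho_max, length.out = 200)
  eta <- ross_minton_eval(x, rho)
  graphics::plot(rho, eta,
    type = "l", col = "blue", lwd = 2,
    xlab = "concentration [mg/mL]", ylab = "viscosity [mPa s]", ...
  )
  if (!is.null(band)) {
    bb <- band$band(rho)
    graphics::polygon(c(rho, rev(rho)), c(bb[, 1], rev(bb[, 2])),
      col = grDevices::adjustcolor("blue", 0.15), border = NA
    )
  }
  if (!is.null(data)) {
    graphics::points(data$concentration, data$viscosity,
      pch = ifelse(data$filtered, 16, 17),
      col = ifelse(data$filtered, "black", "darkorange")
    )
  }
  invisible(x)
}
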