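#' Power-law fit to the inter-trajectory standard deviation
#'
#' The pointwise standard deviation of the per-trajectory running integrals
#' grows with lag time approximately as `sigma(t) = A * t^b` (A, b > 0).
#' The exponent b sets the weighting of the subsequent multi-exponential fit
#' of the ensemble mean. The fit is a linear regression of `log sigma` on
#' `log t`, which is exact on noiseless power laws and guarantees A > 0 by
#' construction; t = 0 is always excluded (sigma(0) = 0).
#'
#' @param x a `gk_ensemble` (its `sigma_curve` is used), or a numeric vector
#'   of times \[ps\].
#' @param sigma if `x` is a numeric time vector, the matching sigma values
#'   \[mPa.s\].
#' @param fit_range length-2 numeric, time window \[ps\] to fit inside;
#'   default the full positive-time range.
#' @return object of class `power_law_fit`: `A` \[mPa.s ps^-b\], `b`,
#'   `fit_range`, `residual_norm` (RMS of log-space residuals), `n_points`.
#' @export
fit_power_law <- function(x, sigma = NULL, fit_range = NULL) {
  if (inherits(x, "gk_ensemble")) {
    times <- x$times
    sigma <- x$sigma_curve
  } else {
    times <- x
    if (is.null(sigma)) stop("fit_power_law: sigma values required")
  }
  stopifnot(length(times) == length(sigma))
  if (is.null(fit_range)) fit_range <- range(times[times > 0])
  sel <- times > 0 & times >= fit_range[1] & times <= fit_range[2]
  if (sum(sel) < 10) stop("fit_power_law: fewer than 10 positive-time points in range")
  if (any(sigma[sel] <= 0)) {
    stop(
      "fit_power_law: sigma(t) <= 0 inside the fit range ",
      "(degenerate ensemble, e.g. identical trajectories)"
    )
  }
  lt <- log(times[sel])
  ls <- log(sigma[sel])
  co <- stats::lm.fit(cbind(1, lt), ls)
  A <- exp(co$coefficients[[1]])
  b <- co$coefficients[[2]]
  if (!is.finite(b) || b <= 0) {
    stop(
      "fit_power_law: fitted exponent b = ", signif(b, 4),
      " is not positive; sigma(t) does not grow with time"
    )
  }
  structure(
    list(
      A = A, b = b, fit_range = fit_range,
      residual_norm = sqrt(mean(co$residuals^2)), n_points = sum(sel)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law fit sigma(t) = A t^b:\n")
  cat(
    "  A =", signif(x$A, 5), "mPa.s ps^-b,  b =", signif(x$b, 5),
    " (", x$n_points, "points, rms log-residual",
    signif(x$residual_norm, 3), ")\n"
  )
  invisible(x)
}

# Saturating multi-exponential running-integral model.
# Triexponential:
#   eta(t) = B [ a t1 (1-exp(-t/t1)) + b t2 (1-exp(-t/t2))
#                + (1-a-b) t3 (1-exp(-t/t3)) ],
# the time integral of an ACF that decays as a sum of three exponentials.
# Biexponential drops the beta term (amplitudes a and 1-a).
.multiexp_eval <- function(t, B, amps, taus) {
  acc <- 0
  for (i in seq_along(taus)) {
    acc <- acc + amps[i] * taus[i] * (1 - exp(-t / taus[i]))
  }
  B * acc
}

# Unconstrained parameterisation: theta -> (B, amps, taus).
# B = exp(theta[1]); amplitudes via softmax (sum to 1, each in (0,1));
# taus = cumsum(exp(.)) which enforces 0 < tau1 <= tau2 <= tau3.
.multiexp_decode <- function(theta, k) {
  B <- exp(theta[1])
  if (k == 1) {
    amps <- 1
    taus <- exp(theta[2])
  } else {
    a_raw <- c(theta[2:k], 0)
    e <- exp(a_raw - max(a_raw))
    amps <- e / sum(e)
    taus <- cumsum(exp(theta[(k + 1):(2 * k)]))
  }
  list(B = B, amps = amps, taus = taus)
}

.multiexp_encode <- function(B, amps, taus) {
  k <- length(taus)
  amps <- pmax(amps, 1e-8)
  amps <- amps / sum(amps)
  if (k == 1) {
    return(c(log(B), log(taus)))
  }
  c(log(B), log(amps[1:(k - 1)]) - log(amps[k]), log(c(taus[1], diff(taus))))
}

#' Weighted multi-exponential fit of the mean running integral
#'
#' Fits the ensemble-mean running viscosity `<eta(t)>` with the saturating
#' multi-exponential
#' `eta(t) = B * [alpha tau1 (1 - e^(-t/tau1)) + beta tau2 (1 - e^(-t/tau2))
#' + (1 - alpha - beta) tau3 (1 - e^(-t/tau3))]`
#' (biexponential: beta term absent), subject to `B > 0`,
#' `0 <= alpha, beta, alpha + beta <= 1`, `tau1 <= tau2 <= tau3 > 0`.
#' Residuals are weighted by `t^(-b)` with the exponent from
#' [fit_power_law()], i.e. inverse-sigma weighting under
#' `sigma(t) = A t^b`: the statistically accurate short-time data dominate
#' while the fit form still absorbs the slow long-time rise. The viscosity
#' estimate is the analytic long-time limit
#' `eta_inf = B * (alpha tau1 + beta tau2 + (1 - alpha - beta) tau3)`.
#'
#' Optimisation is Levenberg-Marquardt on an unconstrained reparameterisation
#' (log B, softmax amplitudes, log tau increments), restarted from
#' `restarts` initial points with time constants log-spaced across the fit
#' window; the best weighted residual wins.
#'
#' @param x a `gk_ensemble` (its `mean_curve` is fitted) or a numeric time
#'   vector \[ps\].
#' @param eta if `x` is a time vector, the curve values \[mPa.s\].
#' @param b weighting exponent from [fit_power_law()] (or a `power_law_fit`);
#'   `b = 0` disables weighting (used when no sigma curve exists).
#' @param form `"triexponential"` (default) or `"biexponential"`.
#' @param fit_range length-2 time window \[ps\]; default all positive times.
#' @param restarts number of multi-start initialisations (default 16).
#' @param seed integer seed for the multi-start jitter; fixed default 1 for
#'   reproducibility.
#' @param thin keep every `thin`-th point of the curve before fitting
#'   (default 1 = all); fit results are insensitive to moderate thinning
#'   because neighbouring points of a running integral are strongly
#'   correlated.
#' @return object of class `multiexp_fit`: `form`, `B`, `alpha`, `beta`,
#'   `tau` (ordered), `eta_infinity` \[mPa.s\], `weight_exponent_b`,
#'   `fit_range`, `residual_norm` (weighted RMS), `converged`, `n_points`.
#' @export
fit_multiexponential <- function(x, eta = NULL, b = 0,
                                 form = c("triexponential", "biexponential"),
                                 fit_range = NULL, restarts = 16, seed = 1,
                                 thin = 1) {
  form <- match.arg(form)
  if (inherits(x, "gk_ensemble")) {
    times <- x$times
    eta <- x$mean_curve
  } else {
    times <- x
    if (is.null(eta)) stop("fit_multiexponential: eta values required")
  }
  if (inherits(b, "power_law_fit")) b <- b$b
  stopifnot(length(times) == length(eta), is.numeric(b), length(b) == 1)
  if (is.null(fit_range)) fit_range <- range(times[times > 0])
  sel <- which(times > 0 & times >= fit_range[1] & times <= fit_range[2])
  if (thin > 1) sel <- sel[seq(1, length(sel), by = thin)]
  if (length(sel) < 10) stop("fit_multiexponential: fit range has fewer than 10 points")
  tt <- times[sel]
  yy <- eta[sel]
  w <- tt^(-b)
  w <- w / mean(w) # scale-free weights
  k <- if (form == "triexponential") 3L else 2L

  # a time constant much longer than the fitted window is not identifiable
  # and would extrapolate eta_infinity arbitrarily; softly bound tau at
  # twice the window end
  tau_cap <- 2 * max(tt)
  pen_scale <- 1e3 * sqrt(sum((w * yy)^2))
  resid_fn <- function(theta) {
    p <- .multiexp_decode(theta, k)
    pen <- pen_scale * max(0, log(p$taus[k] / tau_cap))
    c(w * (yy - .multiexp_eval(tt, p$B, p$amps, p$taus)), pen)
  }

  # initial guesses: taus log-spaced across [10 dt, t_max / 2], equal
  # amplitudes, B from the curve's final value
  dt <- tt[2] - tt[1]
  t_lo <- max(10 * dt, tt[1])
  t_hi <- max(tt) / 2
  if (t_hi <= t_lo) t_hi <- 2 * t_lo
  y_end <- max(yy[length(yy)], .Machine$double.eps)

  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit(
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    )
  }

  best <- NULL
  n_fail <- 0L
  for (r in seq_len(restarts)) {
    span <- stats::runif(1, 0.5, 1) * (log(t_hi) - log(t_lo))
    off <- stats::runif(1, 0, log(t_hi) - log(t_lo) - span)
    taus0 <- exp(log(t_lo) + off + span * seq(0, 1, length.out = k))
    amps0 <- stats::runif(k, 0.5, 1.5)
    amps0 <- amps0 / sum(amps0)
    B0 <- y_end / sum(amps0 * taus0)
    theta0 <- .multiexp_encode(B0, amps0, taus0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !all(is.finite(fit$par))) {
      n_fail <- n_fail + 1L
      next
    }
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    stop("fit_multiexponential: no restart converged (", n_fail, " failures)")
  }
  p <- .multiexp_decode(best$par, k)
  amps <- p$amps
  eta_inf <- p$B * sum(amps * p$taus)
  structure(
    list(
      form = form, B = p$B,
      alpha = amps[1], beta = if (k == 3) amps[2] else NA_real_,
      tau = p$taus, eta_infinity = eta_inf, weight_exponent_b = b,
      fit_range = fit_range,
      residual_norm = sqrt(best$rss / length(tt)),
      converged = TRUE, n_restarts_failed = n_fail, n_points = length(tt)
    ),
    class = "multiexp_fit"
  )
}

#' Evaluate a fitted multi-exponential running-integral model
#'
#' @param object a `multiexp_fit`.
#' @param times times \[ps\] at which to evaluate.
#' @param ... unused.
#' @return eta(t) \[mPa.s\] at `times`.
#' @export
predict.multiexp_fit <- function(object, times, ...) {
  amps <- if (object$form == "triexponential") {
    c(object$alpha, object$beta, 1 - object$alpha - object$beta)
  } else {
    c(object$alpha, 1 - object$alpha)
  }
  .multiexp_eval(times, object$B, amps, object$tau)
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(
    "Weighted ", x$form, " fit (t^-b weighting, b = ",
    signif(x$weight_exponent_b, 4), "):\n",
    sep = ""
  )
  amps <- if (x$form == "triexponential") {
    c(x$alpha, x$beta, 1 - x$alpha - x$beta)
  } else {
    c(x$alpha, 1 - x$alpha)
  }
  cat(
    "  tau [ps]:", paste(signif(x$tau, 4), collapse = ", "),
    "  amplitudes:", paste(signif(amps, 3), collapse = ", "), "\n"
  )
  cat(
    "  eta_infinity =", signif(x$eta_infinity, 5), "mPa.s",
    " (weighted rms residual", signif(x$residual_norm, 3), ")\n"
  )
  invisible(x)
}

#' Aggregate per-set viscosities with the between-set uncertainty convention
#'
#' Combines the fit to the all-trajectory mean curve with the fits to the
#' per-set mean curves. The reported uncertainty is, by default, the root of
#' the sum of squared deviations of the set viscosities from their mean
#' (equivalently sample sd times sqrt(n_sets - 1)); for three sets this is a
#' conservative between-set spread. The plain sample standard deviation is
#' available as `convention = "sd"`.
#'
#' @param set_fits list of `multiexp_fit` (one per repeat set), or a numeric
#'   vector of per-set viscosities \[mPa.s\].
#' @param combined_fit `multiexp_fit` to the all-trajectory mean, or a single
#'   numeric viscosity \[mPa.s\].
#' @param convention `"rssd"` (root-sum-of-squared-deviations, default) or
#'   `"sd"` (sample standard deviation).
#' @return object of class `viscosity_estimate`: `combined_eta`, `set_etas`,
#'   `uncertainty`, `uncertainty_sd`, `n_sets`, `convention`.
#' @export
#' @examples
#' aggregate_sets(c(7.5, 14.4, 7.2), 9.2) # uncertainty 5.8
aggregate_sets <- function(set_fits, combined_fit,
                           convention = c("rssd", "sd")) {
  convention <- match.arg(convention)
  set_etas <- if (is.numeric(set_fits)) {
    set_fits
  } else {
    vapply(set_fits, function(f) f$eta_infinity, numeric(1))
  }
  if (length(set_etas) < 2) stop("aggregate_sets: need at least 2 sets")
  combined_eta <- if (is.numeric(combined_fit)) {
    combined_fit
  } else {
    combined_fit$eta_infinity
  }
  dev2 <- (set_etas - mean(set_etas))^2
  rssd <- sqrt(sum(dev2))
  ssd <- sqrt(sum(dev2) / (length(set_etas) - 1))
  structure(
    list(
      combined_eta = combined_eta, set_etas = set_etas,
      uncertainty = if (convention == "rssd") rssd else ssd,
      uncertainty_sd = ssd, n_sets = length(set_etas),
      convention = convention
    ),
    class = "viscosity_estimate"
  )
}

#' @export
print.viscosity_estimate <- function(x, ...) {
  cat(
    "Viscosity estimate: ", signif(x$combined_eta, 3), " +/- ",
    signif(x$uncertainty, 2), " mPa.s\n",
    sep = ""
  )
  cat(
    "  per-set values [mPa.s]:", paste(signif(x$set_etas, 3), collapse = ", "),
    sprintf("(%s convention)\n", x$convention)
  )
  invisible(x)
}

#' Truncation robustness check
#'
#' Re-runs the weighted multi-exponential fit on a truncated time window
#' (e.g. the first fifth of the running integrals) so the stability of the
#' long-time viscosity against the fitted range can be assessed. When the
#' largest fitted time constant is comparable to the truncation time the
#' truncated estimate is biased low.
#'
#' @param x a `gk_ensemble` or numeric time vector (see
#'   [fit_multiexponential()]).
#' @param eta curve values when `x` is a time vector.
#' @param b weighting exponent.
#' @param form fit form.
#' @param truncated_range length-2 time window \[ps\], strictly inside the
#'   available range.
#' @param ... passed to [fit_multiexponential()].
#' @return a `multiexp_fit` on the truncated window.
#' @export
truncation_check <- function(x, eta = NULL, b = 0,
                             form = c("triexponential", "biexponential"),
                             truncated_range, ...) {
  times <- if (inherits(x, "gk_ensemble")) x$times else x
  if (truncated_range[2] >= max(times)) {
    stop("truncation_check: truncated_range must end before the full range")
  }
  fit_multiexponential(x, eta,
    b = b, form = form,
    fit_range = truncated_range, ...
  )
}
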