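#' Bootstrap convergence of the viscosity versus ensemble size
#'
#' Quantifies how the time-decomposition viscosity estimate converges with
#' the number of trajectories: for each subset size `s`, draws
#' `draws_per_size` random subsets of `s` distinct trajectories (without
#' replacement within a draw), averages their running integrals, runs the
#' full two-stage fit (power law on the subset's sigma(t), then the
#' t^(-b)-weighted multi-exponential on the subset mean), and reports the
#' mean and standard deviation of the resulting long-time viscosities.
#'
#' @param ensemble a `gk_ensemble` of per-trajectory running integrals.
#' @param subset_sizes strictly increasing subset sizes, each `<= n`;
#'   default `seq(10, 60, 10)`.
#' @param draws_per_size independent draws per size (default 100).
#' @param b_source `"refit"` (default): the power-law exponent is refit on
#'   each subset's sigma(t); `"fixed"`: `b_fixed` is reused for all draws.
#' @param b_fixed exponent used when `b_source = "fixed"`.
#' @param form,fit_range,restarts,thin passed to [fit_multiexponential()].
#' @param seed integer; the draw sequence and fit restarts are fully
#'   determined by it.
#' @return object of class `bootstrap_result`: `subset_sizes`,
#'   `draws_per_size`, `mean_eta`, `std_eta` \[mPa.s\], `n_failures`
#'   (per-size count of draws where every restart failed), `seed`.
#' @export
bootstrap_viscosity <- function(ensemble, subset_sizes = seq(10, 60, 10),
                                draws_per_size = 100,
                                b_source = c("refit", "fixed"),
                                b_fixed = NULL,
                                form = "triexponential", fit_range = NULL,
                                restarts = 4, thin = 1, seed = 1) {
  b_source <- match.arg(b_source)
  stopifnot(inherits(ensemble, "gk_ensemble"), draws_per_size >= 2)
  n <- ensemble$n
  subset_sizes <- as.integer(subset_sizes)
  if (any(diff(subset_sizes) <= 0)) {
    stop("bootstrap_viscosity: subset_sizes must be strictly increasing")
  }
  if (max(subset_sizes) > n) {
    stop(
      "bootstrap_viscosity: largest subset size (", max(subset_sizes),
      ") exceeds the ensemble size (", n, ")"
    )
  }
  if (b_source == "fixed" && is.null(b_fixed)) {
    stop("bootstrap_viscosity: b_fixed required when b_source = 'fixed'")
  }
  times <- ensemble$times
  m <- ensemble$eta_mat
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  )

  mean_eta <- std_eta <- numeric(length(subset_sizes))
  n_fail <- integer(length(subset_sizes))
  for (si in seq_along(subset_sizes)) {
    s <- subset_sizes[si]
    etas <- rep(NA_real_, draws_per_size)
    for (d in seq_len(draws_per_size)) {
      idx <- sample.int(n, s, replace = FALSE)
      sub <- m[, idx, drop = FALSE]
      mu <- rowMeans(sub)
      b <- if (b_source == "fixed") {
        b_fixed
      } else if (s >= 2) {
        sig <- sqrt(rowSums((sub - mu)^2) / (s - 1))
        tryCatch(
          fit_power_law(times, sig, fit_range = fit_range)$b,
          error = function(e) NA_real_
        )
      } else {
        NA_real_
      }
      if (is.na(b)) b <- 0 # degenerate subset: fall back to unweighted fit
      # fit seed derived from the subset so identical draws give identical
      # fits (size-N subsets then have exactly zero spread)
      fit_seed <- as.integer(
        (as.numeric(seed) * 1009 + sum(sort(idx) * seq_len(s))) %% 2147483587
      )
      fit <- tryCatch(
        fit_multiexponential(times, mu,
          b = b, form = form,
          fit_range = fit_range, restarts = restarts,
          thin = thin, seed = fit_seed
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        n_fail[si] <- n_fail[si] + 1L
      } else {
        etas[d] <- fit$eta_infinity
      }
    }
    ok <- etas[!is.na(etas)]
    mean_eta[si] <- mean(ok)
    std_eta[si] <- stats::sd(ok)
  }
  structure(
    list(
      subset_sizes = subset_sizes, draws_per_size = draws_per_size,
      mean_eta = mean_eta, std_eta = std_eta, n_failures = n_fail,
      seed = seed
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(
    "Bootstrap convergence (", x$draws_per_size,
    " draws per size, without replacement):\n",
    sep = ""
  )
  df <- data.frame(
    size = x$subset_sizes, mean_eta = signif(x$mean_eta, 4),
    std_eta = signif(x$std_eta, 3), failures = x$n_failures
  )
  print(df, row.names = FALSE)
  invisible(x)
}
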