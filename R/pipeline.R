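#' Per-trajectory running viscosity curves from an ensemble layout
#'
#' For each trajectory: form the statistical channels
#' ([combine_components()]), average the channel ACFs
#' ([average_acfs()]), and integrate ([running_integral()]). The per-
#' trajectory curves are then stacked into a `gk_ensemble` with the layout's
#' set partition, ready for the time-decomposition fit.
#'
#' @param layout an [ensemble_layout()].
#' @param max_lag largest ACF lag \[ps\]; default the full series span.
#' @param estimator ACF normalisation, see [compute_acf()].
#' @param subtract_mean see [compute_acf()].
#' @return a `gk_ensemble`.
#' @export
gk_curves <- function(layout, max_lag = NULL,
                      estimator = c("unbiased", "biased"),
                      subtract_mean = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(layout, "ensemble_layout"))
  curves <- lapply(layout$trajectories, function(tr) {
    cs <- combine_components(tr)
    a <- average_acfs(list(cs),
      max_lag = max_lag, estimator = estimator,
      subtract_mean = subtract_mean
    )
    running_integral(a, tr$volume, tr$temperature, source = tr$trajectory_id)
  })
  build_ensemble(curves, sets = layout$sets)
}

#' Running viscosity curves from a synthetic OU ensemble, streaming
#'
#' Equivalent to `gk_curves(generate_ensemble(spec, n, sets), ...)` but
#' processes one trajectory at a time so that long synthetic ensembles never
#' reside in memory at once. Identical seed and layout give the identical
#' result as the materialised route.
#'
#' @param spec an [ou_spec()].
#' @param n_trajectories number of trajectories (divisible by `sets`).
#' @param sets number of repeat sets.
#' @param max_lag largest ACF lag \[ps\].
#' @param estimator ACF normalisation.
#' @return a `gk_ensemble`.
#' @export
synthetic_gk_ensemble <- function(spec, n_trajectories, sets = 1,
                                  max_lag = NULL,
                                  estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(spec, "ou_spec"))
  if (n_trajectories %% sets != 0) {
    stop("synthetic_gk_ensemble: n_trajectories must be divisible by sets")
  }
  per_set <- n_trajectories %/% sets
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  )
  curves <- vector("list", n_trajectories)
  set_ids <- character(n_trajectories)
  for (j in seq_len(n_trajectories)) {
    set_ids[j] <- sprintf("set%d", (j - 1) %/% per_set + 1)
    tr <- .ou_trajectory(spec, sprintf("traj%02d", j), set_ids[j])
    cs <- combine_components(tr)
    a <- average_acfs(list(cs), max_lag = max_lag, estimator = estimator)
    curves[[j]] <- running_integral(a, tr$volume, tr$temperature,
      source = tr$trajectory_id
    )
  }
  build_ensemble(curves, sets = split(seq_len(n_trajectories), set_ids))
}

#' Time-decomposition viscosity estimate for a curve ensemble
#'
#' Runs the two-stage fitting protocol on a `gk_ensemble`: power-law fit
#' `A t^b` to the inter-trajectory sigma(t), then the t^(-b)-weighted
#' multi-exponential fit to the all-trajectory mean and to each per-set mean
#' curve, aggregated with the between-set uncertainty convention. With a
#' single trajectory (no sigma curve) the power-law stage is skipped with a
#' warning and the fit is unweighted.
#'
#' @param ensemble a `gk_ensemble` (from [gk_curves()] or
#'   [synthetic_gk_ensemble()]).
#' @param form fit form, `"triexponential"` (default) or `"biexponential"`.
#' @param fit_range time window \[ps\] for both fits; default full range.
#' @param restarts multi-start count for the multi-exponential fit.
#' @param seed seed for the multi-start jitter.
#' @param thin fit every `thin`-th curve point (see
#'   [fit_multiexponential()]).
#' @param convention uncertainty convention, see [aggregate_sets()].
#' @return list with `power_law` (`power_law_fit` or `NULL`),
#'   `combined_fit`, `set_fits` (named list), and `estimate`
#'   (`viscosity_estimate`, `NULL` when fewer than 2 sets).
#' @export
estimate_viscosity <- function(ensemble, form = "triexponential",
                               fit_range = NULL, restarts = 16, seed = 1,
                               thin = 1, convention = "rssd") {
  stopifnot(inherits(ensemble, "gk_ensemble"))
  pl <- NULL
  b <- 0
  if (ensemble$n >= 2 && all(is.finite(ensemble$sigma_curve)) &&
    any(ensemble$sigma_curve > 0)) {
    pl <- fit_power_law(ensemble, fit_range = fit_range)
    b <- pl$b
  } else {
    warning(
      "estimate_viscosity: sigma(t) unavailable or degenerate; ",
      "skipping the power-law stage and fitting unweighted"
    )
  }
  combined <- fit_multiexponential(ensemble,
    b = b, form = form,
    fit_range = fit_range, restarts = restarts, seed = seed, thin = thin
  )
  set_fits <- NULL
  est <- NULL
  if (!is.null(ensemble$set_means) && length(ensemble$set_means) >= 2) {
    set_fits <- lapply(ensemble$set_means, function(mu) {
      fit_multiexponential(ensemble$times, mu,
        b = b, form = form,
        fit_range = fit_range, restarts = restarts, seed = seed, thin = thin
      )
    })
    est <- aggregate_sets(set_fits, combined, convention = convention)
  }
  list(power_law = pl, combined_fit = combined, set_fits = set_fits, estimate = est)
}

.default_config <- list(
  # input
  files = NULL, volume = NULL, temperature = NULL,
  column_map = c(xy = 2, xz = 3, yz = 4), set_ids = NULL,
  # acf
  max_lag = NULL, estimator = "unbiased", subtract_mean = FALSE,
  # fits
  form = "triexponential", fit_range = NULL, restarts = 16, seed = 1,
  thin = 1, convention = "rssd", b_mode = "refit",
  # synthetic
  synth = NULL, # list(amplitudes, timescales, time_step, n_steps, volume,
  # temperature, n_trajectories, sets)
  # bootstrap
  subset_sizes = seq(10, 60, 10), draws_per_size = 100, boot_restarts = 4,
  # rheology
  rheo_file = NULL, rheo_eta0_mode = "fitted", rheo_eta0 = NULL,
  rheo_uncertainty = 0.10, invert_at = NULL,
  # output
  out_dir = "."
)

#' Build a run configuration
#'
#' Collects every pipeline option with documented defaults. Configurations
#' round-trip losslessly through YAML ([write_run_config()],
#' [read_run_config()]), and every option can be overridden by argument.
#'
#' @param ... named overrides of the defaults (unknown names are an error).
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  over <- list(...)
  cfg <- .default_config
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("run_config: unknown option(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file location.
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  # yaml drops names of atomic vectors; store the column map as a mapping
  if (!is.null(vals$column_map)) vals$column_map <- as.list(vals$column_map)
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'")
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$column_map)) vals$column_map <- unlist(vals$column_map)
  do.call(run_config, vals)
}

.write_table <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

.load_layout <- function(config) {
  if (!is.null(config$synth)) {
    s <- config$synth
    spec <- ou_spec(
      s$amplitudes, s$timescales, s$time_step, s$n_steps,
      s$volume, s$temperature,
      n_channels = s$n_channels %||% 6,
      seed = s$seed %||% config$seed
    )
    return(generate_ensemble(spec, s$n_trajectories, s$sets %||% 1))
  }
  if (is.null(config$files)) stop("config: neither 'files' nor 'synth' given")
  missing <- config$files[!file.exists(config$files)]
  if (length(missing)) {
    stop("config: input file(s) not found: ", paste(missing, collapse = ", "))
  }
  set_ids <- config$set_ids %||% rep("set1", length(config$files))
  trajs <- lapply(seq_along(config$files), function(i) {
    read_xvg(config$files[i], config$volume, config$temperature,
      column_map = config$column_map, set_id = set_ids[i]
    )
  })
  ensemble_layout(trajs)
}

#' Run the full viscosity pipeline from a configuration
#'
#' Reads (or synthesises) the trajectory ensemble, computes the ensemble
#' ACF, per-trajectory and mean running integrals and sigma(t), performs the
#' two-stage time-decomposition fit per set and combined, and writes every
#' intermediate as delimited text into `config$out_dir` together with a
#' machine-readable YAML summary.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the [estimate_viscosity()] result, with the `gk_ensemble`
#'   attached as `$ensemble`, invisibly.
#' @export
run_viscosity <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  layout <- .load_layout(config)
  say(
    "ensemble: ", length(layout$trajectories), " trajectories in ",
    length(layout$sets), " sets"
  )
  ens <- gk_curves(layout,
    max_lag = config$max_lag, estimator = config$estimator,
    subtract_mean = config$subtract_mean
  )
  res <- estimate_viscosity(ens,
    form = config$form, fit_range = config$fit_range,
    restarts = config$restarts, seed = config$seed, thin = config$thin,
    convention = config$convention
  )
  res$ensemble <- ens

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  op <- function(f) file.path(config$out_dir, f)
  curves <- data.frame(time = ens$times, mean_eta = ens$mean_curve, sigma = ens$sigma_curve)
  if (!is.null(ens$set_means)) {
    for (nm in names(ens$set_means)) curves[[nm]] <- ens$set_means[[nm]]
  }
  .write_table(curves, op("running_integrals.tsv"))
  .write_table(
    data.frame(time = ens$times, ens$eta_mat, check.names = FALSE),
    op("per_trajectory_eta.tsv")
  )
  summary <- list(
    n_trajectories = ens$n,
    power_law = if (!is.null(res$power_law)) {
      list(A = res$power_law$A, b = res$power_law$b)
    },
    combined_eta = res$combined_fit$eta_infinity,
    set_etas = if (!is.null(res$estimate)) as.list(res$estimate$set_etas),
    uncertainty = if (!is.null(res$estimate)) res$estimate$uncertainty,
    form = config$form, seed = config$seed,
    estimator = config$estimator,
    max_lag = config$max_lag %||% "full", restarts = config$restarts
  )
  yaml::write_yaml(summary, op("viscosity_summary.yaml"), precision = 15)
  say(
    "combined eta = ", signif(res$combined_fit$eta_infinity, 4), " mPa.s",
    if (!is.null(res$estimate)) {
      paste0(" +/- ", signif(res$estimate$uncertainty, 3))
    }
  )
  invisible(res)
}

#' Run the bootstrap convergence analysis from a configuration
#'
#' @param config a [run_config()].
#' @param ensemble optional precomputed `gk_ensemble` (skips the input
#'   stage).
#' @param quiet suppress progress messages.
#' @return a `bootstrap_result`, invisibly; also written as TSV.
#' @export
run_bootstrap <- function(config, ensemble = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(ensemble)) {
    layout <- .load_layout(config)
    ensemble <- gk_curves(layout,
      max_lag = config$max_lag,
      estimator = config$estimator
    )
  }
  b_fixed <- NULL
  if (config$b_mode == "fixed") {
    b_fixed <- fit_power_law(ensemble, fit_range = config$fit_range)$b
  }
  br <- bootstrap_viscosity(ensemble,
    subset_sizes = config$subset_sizes,
    draws_per_size = config$draws_per_size,
    b_source = config$b_mode, b_fixed = b_fixed,
    form = config$form, fit_range = config$fit_range,
    restarts = config$boot_restarts, thin = config$thin,
    seed = config$seed
  )
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_table(
    data.frame(
      size = br$subset_sizes, mean_eta = br$mean_eta,
      std_eta = br$std_eta, failures = br$n_failures
    ),
    file.path(config$out_dir, "bootstrap.tsv")
  )
  if (!quiet) print(br)
  invisible(br)
}

#' Run the rheometry analysis from a configuration
#'
#' Fits the Ross-Minton equation to a rheometry table, computes the
#' concentration-uncertainty band, and optionally inverts the fitted curve
#' at supplied viscosities.
#'
#' @param config a [run_config()] with `rheo_file` set (default: the bundled
#'   mAb dataset at 297 K).
#' @param quiet suppress progress messages.
#' @return list with `fit`, `band`, `inversions` (data.frame or `NULL`),
#'   invisibly; also written as text.
#' @export
run_rheo <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  path <- config$rheo_file %||%
    system.file("extdata", "mab_rheometry_297K.tsv", package = "gkvisc")
  data <- read_rheo_table(path)
  fit <- ross_minton_fit(data,
    eta0_mode = config$rheo_eta0_mode,
    eta0_value = config$rheo_eta0
  )
  band <- concentration_uncertainty_band(data, config$rheo_uncertainty,
    eta0_mode = config$rheo_eta0_mode, eta0_value = config$rheo_eta0
  )
  inversions <- NULL
  if (!is.null(config$invert_at)) {
    inversions <- data.frame(
      viscosity = config$invert_at,
      concentration = invert_concentration(fit, config$invert_at)
    )
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(
    list(
      eta0 = fit$eta0, intrinsic_viscosity = fit$intrinsic_viscosity,
      crowding_ratio = fit$crowding_ratio,
      inversions = if (!is.null(inversions)) {
        stats::setNames(as.list(inversions$concentration), inversions$viscosity)
      }
    ),
    file.path(config$out_dir, "rheo_summary.yaml"),
    precision = 15
  )
  if (!quiet) {
    print(fit)
    if (!is.null(inversions)) print(inversions)
  }
  invisible(list(fit = fit, band = band, inversions = inversions))
}
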