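#' Specification of a synthetic Ornstein-Uhlenbeck pressure ensemble
#'
#' Defines a stationary Gaussian pressure-fluctuation model whose channels
#' are independent sums of Ornstein-Uhlenbeck (OU) modes. The autocorrelation
#' of each channel is exactly `sum_i c_i * exp(-t / tau_i)`, so the
#' Green-Kubo integral — and hence the viscosity — is known in closed form:
#' the generator is an exact oracle for the whole analysis pipeline. Real
#' pressure ACFs show fast oscillatory decay at short times and a slow tail;
#' a spread of tau modes over two or more decades emulates that structure
#' (without the oscillations, which integrate to little).
#'
#' @param amplitudes per-mode variances `c_i` \[bar^2\], all > 0.
#' @param timescales per-mode correlation times `tau_i` \[ps\], all > 0.
#' @param time_step sampling interval \[ps\].
#' @param n_steps samples per trajectory, >= 2.
#' @param volume box volume \[nm^3\].
#' @param temperature temperature \[K\].
#' @param n_channels channels per trajectory (6 = off-diagonals plus
#'   diagonal differences, 3 = off-diagonals only).
#' @param seed integer RNG seed.
#' @return object of class `ou_spec`.
#' @export
ou_spec <- function(amplitudes, timescales, time_step, n_steps,
                    volume, temperature, n_channels = 6, seed = 1) {
  stopifnot(
    length(amplitudes) == length(timescales), length(amplitudes) >= 1,
    all(amplitudes > 0), all(timescales > 0), time_step > 0,
    n_steps >= 2, volume > 0, temperature > 0, n_channels %in% c(3, 6)
  )
  structure(
    list(
      amplitudes = amplitudes, timescales = timescales,
      time_step = time_step, n_steps = as.integer(n_steps),
      volume = volume, temperature = temperature,
      n_channels = as.integer(n_channels), seed = as.integer(seed)
    ),
    class = "ou_spec"
  )
}

#' Closed-form Green-Kubo viscosity of an OU spec
#'
#' For an ACF `sum_i c_i * exp(-t / tau_i)` the Green-Kubo integral is
#' `sum_i c_i * tau_i`, so the viscosity is
#' `unit_factor(V, T) * sum_i c_i * tau_i` exactly.
#'
#' @param spec an [ou_spec()].
#' @return viscosity \[mPa.s\].
#' @export
analytic_viscosity <- function(spec) {
  stopifnot(inherits(spec, "ou_spec"))
  unit_factor(spec$volume, spec$temperature) *
    sum(spec$amplitudes * spec$timescales)
}

# One stationary OU-sum path of length n. Exact discrete update per mode:
#   x[k+1] = x[k] * exp(-dt/tau) + sqrt(c * (1 - exp(-2 dt/tau))) * xi,
# initialised from the stationary distribution N(0, c). No time-step bias.
.ou_sum_path <- function(n, dt, amplitudes, timescales) {
  x <- numeric(n)
  for (i in seq_along(amplitudes)) {
    a <- exp(-dt / timescales[i])
    innov <- stats::rnorm(n, sd = sqrt(amplitudes[i] * (1 - a^2)))
    x0 <- stats::rnorm(1, sd = sqrt(amplitudes[i]))
    innov[1] <- a * x0 + innov[1]
    x <- x + as.numeric(stats::filter(innov, a, method = "recursive"))
  }
  x
}

# One synthetic trajectory. Consumes RNG state sequentially; callers seed.
# Off-diagonals xy, xz, yz are independent OU sums with the spec ACF.
# Diagonals xx, yy, zz are independent OU sums with per-mode amplitude
# 2*c_i, so each difference channel (Paa - Pbb)/2 has variance
# (2c + 2c)/4 = c per mode and exactly the spec ACF. The three difference
# channels are marginally correct but mutually correlated — unavoidable,
# since (Pxx-Pyy)/2 = (Pxx-Pzz)/2 - (Pyy-Pzz)/2 identically. Raw synthetic
# diagonals carry no physical meaning.
.ou_trajectory <- function(spec, trajectory_id, set_id) {
  n <- spec$n_steps
  dt <- spec$time_step
  comps <- list()
  for (lab in c("xy", "xz", "yz")) {
    comps[[lab]] <- .ou_sum_path(n, dt, spec$amplitudes, spec$timescales)
  }
  if (spec$n_channels == 6) {
    for (lab in c("xx", "yy", "zz")) {
      comps[[lab]] <- .ou_sum_path(n, dt, 2 * spec$amplitudes, spec$timescales)
    }
  }
  pressure_series(comps, dt, spec$volume, spec$temperature,
    trajectory_id = trajectory_id, set_id = set_id
  )
}

#' Generate a synthetic pressure-tensor ensemble
#'
#' Draws `n_trajectories` independent trajectories from the OU model and
#' partitions them into `sets` equal repeat sets (mirroring an MD design of
#' several repeat simulations each spawning a family of production runs).
#' The RNG is fully determined by `spec$seed`: identical spec and layout
#' give a bit-identical ensemble.
#'
#' @param spec an [ou_spec()].
#' @param n_trajectories number of trajectories; must be divisible by `sets`.
#' @param sets number of repeat sets.
#' @return an [ensemble_layout()].
#' @export
generate_ensemble <- function(spec, n_trajectories, sets = 1) {
  stopifnot(inherits(spec, "ou_spec"), n_trajectories >= 1, sets >= 1)
  if (n_trajectories %% sets != 0) {
    stop("generate_ensemble: n_trajectories must be divisible by sets")
  }
  per_set <- n_trajectories %/% sets
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  )
  trajs <- vector("list", n_trajectories)
  for (j in seq_len(n_trajectories)) {
    set_id <- sprintf("set%d", (j - 1) %/% per_set + 1)
    trajs[[j]] <- .ou_trajectory(spec, sprintf("traj%02d", j), set_id)
  }
  ensemble_layout(trajs)
}
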