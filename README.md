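# gkvisc

Green-Kubo shear viscosity estimation from equilibrium pressure-tensor
fluctuations, by the time-decomposition fitting protocol, with a companion
rheometry module for comparing simulation against cone-plate measurements of
concentrated protein solutions.

## What problem this solves

By linear response, the shear viscosity of a liquid is

    eta = V / (kB T) * integral_0^inf <P_ab(t0) P_ab(t0 + t)> dt,

the time integral of the off-diagonal pressure-tensor autocorrelation
function (ACF). For viscous, slowly relaxing liquids — the motivating case
is monoclonal-antibody (mAb) solutions at 200-250 mg/mL, with viscosities
around 10-25 mPa·s — the running integral `eta(t)` plateaus only after tens
of nanoseconds and is then dominated by noise, so the plateau cannot be read
off directly. The time-decomposition protocol extracts it anyway:

1. compute per-trajectory running GK integrals over an ensemble of N
   independent trajectories (six statistical channels each: the three
   off-diagonal tensor elements, transpose-averaged, plus the three diagonal
   differences `(Paa - Pbb)/2`);
2. fit the inter-trajectory standard deviation with a power law
   `sigma(t) = A t^b`;
3. fit the ensemble mean `<eta(t)>` with a saturating triexponential,
   weighting residuals by `t^-b`, and report the fit's analytic long-time
   limit as the viscosity.

Per-set fits over repeat-simulation sets give a conservative between-set
uncertainty. A bootstrap module quantifies convergence versus ensemble
size, and an Ornstein-Uhlenbeck synthetic-pressure generator with exactly
known viscosity validates the entire chain end to end. The rheometry module
converts cone-plate torque readings (`eta = 3 M alpha / (2 pi R^3 omega)`),
fits the Ross-Minton concentration-viscosity law
`eta(rho) = eta0 * exp([eta] rho / (1 - (k/v)[eta] rho))`, inverts it, and
propagates concentration uncertainty.

Intended users: simulators computing transport coefficients from
molecular-dynamics pressure traces (GROMACS-style XVG input is supported)
and formulation scientists comparing those predictions with rotational
rheometry.

## Worked example

Validate the pipeline on a synthetic ensemble whose viscosity is known in
closed form (two OU modes, 9 trajectories in 3 sets — small enough to run
in seconds):

```r
library(gkvisc)

spec <- ou_spec(c(0.5, 0.05), c(1, 20), time_step = 0.1, n_steps = 5e4,
  volume = 100, temperature = 298, seed = 21)
analytic_viscosity(spec)
#> [1] 0.0003646

ens <- synthetic_gk_ensemble(spec, 9, sets = 3, max_lag = 400)
res <- estimate_viscosity(ens, thin = 4)
res$power_law
#> Power-law fit sigma(t) = A t^b:
#>   A = 3.1858e-06 mPa.s ps^-b,  b = 0.51005  ( 4000 points, rms log-residual 0.172 )
res$estimate
#> Viscosity estimate: 0.00034 +/- 9.2e-06 mPa.s
#>   per-set values [mPa.s]: 0.000333, 0.000342, 0.000346 (rssd convention)
```

The combined estimate (3.40e-4 mPa·s) sits within 7% of the closed-form
value at this deliberately small scale, and the quoted uncertainty is the
root-sum-of-squared-deviations of the three per-set fits. At the study
scale used in the test suite (63 trajectories of 10^6 steps) the estimate
lands within 1%.

Fitting the bundled mAb rheometry dataset (nine points at 297 K) and
inverting at 9.2 mPa·s, the simulation-derived viscosity of a 200 mg/mL
solution:

```r
d <- read_rheo_table(
  system.file("extdata", "mab_rheometry_297K.tsv", package = "gkvisc"))
fit <- ross_minton_fit(d)
fit
#> Ross-Minton fit (log-space least squares):
#>   eta0 = 1.224 mPa.s ( fitted ),  [eta] = 0.008204 mL/mg,  k/v = 0.2566
#>   singularity at rho = 475.1 mg/mL,  rms log-residual = 0.13
invert_concentration(fit, 9.2)
#> [1] 162.0359
```

That is: the simulated 200 mg/mL solution is as viscous as a measured
solution at ~162 mg/mL, an apparent activity-coefficient ratio of ~0.8
between simulation and experiment.

For real data, `read_xvg()` ingests pressure-tensor time series (time plus
tensor columns, `#`/`@` headers skipped), `ensemble_layout()` groups
trajectories into repeat sets, and `gk_curves()` + `estimate_viscosity()`
run the same protocol. `run_viscosity()`, `run_bootstrap()` and
`run_rheo()` drive everything from a YAML configuration, and
`inst/cli/gkvisc.R` exposes them as a command line
(`Rscript gkvisc.R <acf|visc|bootstrap|synth|rheo> ...`).

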