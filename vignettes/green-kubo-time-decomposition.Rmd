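---
title: "Shear viscosity from equilibrium pressure fluctuations: the time-decomposition protocol"
author: "gkvisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear viscosity from equilibrium pressure fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkvisc)
```

## The estimation problem

The shear (dynamic) viscosity of a liquid is an equilibrium transport
coefficient: by linear response it equals the time integral of the
autocorrelation function (ACF) of the off-diagonal pressure tensor,

$$\eta = \frac{V}{k_B T} \int_0^\infty
  \langle P_{\alpha\beta}(t_0)\, P_{\alpha\beta}(t_0 + t)\rangle\, dt,$$

the Green-Kubo (GK) relation. For simple liquids the ACF decays within
picoseconds and the *running integral* $\eta(t)$ — the integral truncated at
lag $t$ — plateaus quickly. For slow, structured liquids (the motivating
application is concentrated monoclonal-antibody solutions at 200-250 mg/mL,
with viscosities of order 10 mPa·s) the ACF has a long, weak tail: the
plateau arrives only after tens of nanoseconds, by which time the running
integral of any single trajectory is dominated by accumulated noise. Reading
the viscosity "off the plateau" is then ill-defined.

`gkvisc` implements the time-decomposition protocol for this regime:

1. Run $N$ independent trajectories and compute a running GK integral
   $\eta_i(t)$ for each, using six statistical channels per trajectory:
   $P_{xy}, P_{xz}, P_{yz}$ (each averaged with its transpose when
   recorded), plus the diagonal differences $(P_{xx}-P_{yy})/2$,
   $(P_{xx}-P_{zz})/2$, $(P_{yy}-P_{zz})/2$, which carry the same
   shear-stress statistics in an isotropic fluid.
2. Form the ensemble mean $\langle\eta(t)\rangle$ and the inter-trajectory
   standard deviation $\sigma(t)$ (sample, $N-1$ divisor).
3. Fit $\sigma(t) = A\,t^b$ ($A, b > 0$) by linear regression in log-log
   space.
4. Fit $\langle\eta(t)\rangle$ with the saturating triexponential
   $$\eta(t) = B\left[\alpha\tau_1(1 - e^{-t/\tau_1})
     + \beta\tau_2(1 - e^{-t/\tau_2})
     + (1{-}\alpha{-}\beta)\tau_3(1 - e^{-t/\tau_3})\right],$$
   with residuals weighted by $t^{-b}$, and report the analytic asymptote
   $\eta_\infty = B[\alpha\tau_1 + \beta\tau_2 +
   (1{-}\alpha{-}\beta)\tau_3]$ as the viscosity.

The weighting is the crux: the short-time part of
$\langle\eta(t)\rangle$ is statistically precise but systematically below
the asymptote, the long-time part is unbiased but noisy with
$\sigma(t) \sim t^b$. Dividing residuals by the fitted noise law (squared
weights $t^{-2b}$, i.e. inverse-variance) balances the two, and the fitted
functional form carries the extrapolation to $t \to \infty$. The
triexponential is the integral of a triexponential ACF decay; it is treated
as purely empirical, and no physical meaning is attached to the individual
$\tau_i$. A biexponential variant is provided because it suffices for simple
liquids; on slow-rise data its weighted residual is demonstrably worse
(`fit_multiexponential(..., form = "biexponential")`, compared in the test
suite), which is the reason the three-term form is the default.

## Ensemble design and uncertainty convention

The intended data layout mirrors a standard MD design: a few long repeat
simulations, each spawning a family of shorter constant-volume production
runs whose pressure tensors are recorded at a fine cadence (4 fs in the
motivating study; 3 repeats x 21 runs = 63 trajectories of 100 ns each).
`ensemble_layout()` captures this partition. The combined viscosity comes
from fitting the all-trajectory mean; in addition each repeat set's 21-run
mean is fitted separately, and the quoted uncertainty is

$$u = \sqrt{\textstyle\sum_{s}(\eta_s - \bar\eta)^2},$$

the root of the *sum* of squared deviations of the set values (equivalently,
for three sets, the sample standard deviation times $\sqrt{2}$). This
deliberately conservative convention reproduces the published uncertainties
of the motivating study from its per-set values (7.5, 14.4, 7.2 mPa·s give
±5.8; 31.2, 20.3, 24.4 give ±7.8); `aggregate_sets()` also exposes the plain
sample standard deviation (`convention = "sd"`).

```{r}
aggregate_sets(c(7.5, 14.4, 7.2), 9.2)
```

## Numerical choices

**ACF estimator.** `compute_acf()` averages over all time origins by
zero-padded FFT (Wiener-Khinchin); the padded length exceeds
`n + n_lags` so no circular wrap-around contaminates the reported lags, and
the result equals the direct $O(N^2)$ sum to 1e-10 relative (property-tested
against a brute-force oracle). Normalisation is unbiased ($N-k$) by
default — the trapezoidal integral of an unbiased ACF estimate has the
correct expectation at every truncation — with the biased ($N$) variant
available. No mean is subtracted by default: the shear channels average to
zero in an isotropic fluid, and subtracting a noisy sample mean biases the
long-lag tail; a flag enables subtraction for diagnostics.

**Integration.** The running integral uses the cumulative trapezoid on the
uniform lag grid; at a 4 fs cadence the $O(\Delta t^2)$ discretisation error
is negligible against sampling noise.

**Units.** I/O units are fixed (time ps, pressure bar, volume nm³,
temperature K) and converted exactly once: `unit_factor(V, T)` returns
$V \cdot 10^{-29} / (k_B T) \cdot 10^3$ mPa·s per bar²·ps with
$k_B = 1.380649\times 10^{-23}$ J/K exact.

**Fitting.** The power law is fit as a linear regression of
$\log\sigma$ on $\log t$ — exact on noiseless power laws, $A > 0$ by
construction, $t = 0$ excluded (where $\sigma = 0$ and the weight
diverges). The multi-exponential fit is Levenberg-Marquardt
(`minpack.lm::nls.lm`) on an unconstrained reparameterisation: $\log B$,
softmax amplitudes (enforcing $0 \le \alpha, \beta$, $\alpha + \beta \le 1$),
and log increments of $\tau$ (enforcing $0 < \tau_1 \le \tau_2 \le \tau_3$).
Sixteen multi-starts with time constants log-spaced across
$[10\,\Delta t,\ t_{\max}/2]$ and seeded jitter guard against local optima;
the best weighted residual wins, and non-convergence of all restarts is an
error, never silent. On noiseless model curves the asymptote is recovered to
better than 0.1%. One identifiability guard is applied: a time constant far
beyond the fitted window cannot be determined by the data but can extrapolate
$\eta_\infty$ arbitrarily, so $\tau_3$ is softly penalised beyond twice the
window end. Consequently a fit to a window much shorter than the slowest
relaxation (see `truncation_check()`) is biased low — the reason the
protocol prefers fitting the full available range rather than a
short-time truncation.

**Thinning.** Neighbouring points of a running integral are strongly
correlated, so the fits accept a `thin` stride; the study-scale validation
uses every 10th point of a 0.1 ps grid with no measurable effect on the
estimate, at a tenth of the cost.

## The synthetic validation ensemble

`ou_spec()` / `generate_ensemble()` build pressure channels as independent
sums of Ornstein-Uhlenbeck modes with per-mode variance $c_i$ and
correlation time $\tau_i$. The exact discrete update
$x_{n+1} = x_n e^{-\Delta t/\tau} + \sqrt{c(1 - e^{-2\Delta t/\tau})}\,\xi_n$,
initialised from the stationary distribution, has *no* time-discretisation
bias, so the channel ACF is exactly $\sum_i c_i e^{-t/\tau_i}$ and the
Green-Kubo viscosity is exactly
`unit_factor(V, T) * sum(c_i * tau_i)` (`analytic_viscosity()`): the
generator is a closed-form oracle for the entire pipeline.

Two constructions deserve a note. First, synthetic diagonal components are
generated with per-mode variance $2c_i$ so that each diagonal-difference
channel $(P_{aa}-P_{bb})/2$ has exactly the target ACF; the three difference
channels cannot be mutually independent — identically
$(P_{xx}-P_{yy})/2 = (P_{xx}-P_{zz})/2 - (P_{yy}-P_{zz})/2$ — so they are
marginally exact but cross-correlated, which leaves the ensemble mean
unbiased and only reduces the effective channel count. The raw synthetic
diagonals carry no physical meaning. Second, what the OU model does *not*
emulate: the fast oscillatory structure of real pressure ACFs at
sub-picosecond times (which integrates to little), the $t^{-3/2}$
hydrodynamic long-time tail, and any non-Gaussian or non-stationary
behaviour. Passing the synthetic validation therefore demonstrates the
correctness of the estimator chain, not force-field or sampling adequacy on
real trajectories.

The study-scale validation conditions, fixed once: two modes
$c = (0.5, 0.05)$ bar², $\tau = (1, 50)$ ps (a two-decade spread imitating
fast decay plus slow tail), $\Delta t = 0.1$ ps, $10^6$ steps per
trajectory, 63 trajectories in 3 sets of 21 — the published ensemble
design — with ACFs evaluated to a 2000 ps lag (40 slow time constants).
Under these conditions the combined estimate lands within 10% of the
closed-form value, the three set estimates bracket it, and the bootstrap
spread at 60 trajectories covers it within 3 standard deviations.

```{r, eval = FALSE}
spec <- ou_spec(c(0.5, 0.05), c(1, 50), time_step = 0.1, n_steps = 1e6,
  volume = 100, temperature = 298, seed = 42
)
ens <- synthetic_gk_ensemble(spec, 63, sets = 3, max_lag = 2000)
res <- estimate_viscosity(ens, thin = 10)
res$combined_fit$eta_infinity / analytic_viscosity(spec) # ~1.006
```

(A few minutes of compute; the test suite runs exactly this.)

## Bootstrap convergence diagnostics

`bootstrap_viscosity()` quantifies how many trajectories the estimate
needs: for each subset size it draws trajectories *without replacement*
(each trajectory at most once per draw), averages the subset's curves, and
re-runs the full two-stage fit — by default re-fitting $b$ on the subset's
own $\sigma(t)$, since that is the self-consistent reading of the protocol;
a fixed-$b$ mode reuses the full-ensemble exponent for speed. Defaults
follow the published protocol: sizes 10-60, 100 draws per size. The fit seed
is derived from the drawn index set, so identical subsets give identical
fits and the size-$N$ "bootstrap" has exactly zero spread.

## Rheometry companion

Experimental reference viscosities come from cone-plate rheometry:
`cone_plate_viscosity()` converts torque to viscosity via
$\eta = 3M\alpha/(2\pi R^3\omega)$ (small-angle relation; shear stress
$3M/2\pi R^3$ over shear rate $\omega/\alpha$). Concentration dependence is
modelled with the Ross-Minton equation

$$\eta(\rho) = \eta_0 \exp\!\left(\frac{[\eta]\rho}{1 - (k/v)[\eta]\rho}\right),$$

fitted in log-viscosity space (the model is exponential; log space
equalises relative errors across the 2-37 mPa·s range of the bundled
dataset). Only the ratio $k/v$ enters the model, so a single
`crowding_ratio` is fitted. The buffer viscosity $\eta_0$ is not part of
the bundled table; by default it is fitted within [0.5, 2.0] mPa·s — a
bracket that comfortably contains any aqueous buffer near room
temperature — with a fixed-$\eta_0$ mode provided. The curve is strictly
increasing on its domain, so `invert_concentration()` (monotone bracketing,
with the closed form exposed) is well-posed; the ~10% concentration
uncertainty of high-concentration protein samples is propagated by refitting
at $(1\pm u)\rho$ and taking the envelope
(`concentration_uncertainty_band()`).

```{r}
d <- read_rheo_table(
  system.file("extdata", "mab_rheometry_297K.tsv", package = "gkvisc")
)
fit <- ross_minton_fit(d)
fit
invert_concentration(fit, 9.2)
```

The inversion at 9.2 mPa·s — the simulation-derived viscosity of the
200 mg/mL system — gives ca. 162 mg/mL: the simulated solution behaves like
a measured solution at ~0.8 times its nominal concentration, an apparent
activity-coefficient ratio consistent with the one obtained by matching the
simulated 250 mg/mL viscosity to the measured curve (213/250 ≈ 0.85).

## Known limitations

- The triexponential form is empirical; it cannot represent a true
  $t^{-3/2}$ tail, and extrapolation beyond the fitted window inherits the
  form's assumptions.
- The power-law noise model is global over the fit range; if $\sigma(t)$
  crosses over between regimes, a single $b$ is a compromise.
- $\sigma(t)$ requires $N \ge 2$ trajectories; with one trajectory the
  pipeline warns and fits unweighted, which is markedly less reliable.
- The OU oracle validates the estimator, not the physics; agreement on
  synthetic data says nothing about force fields, finite-size effects, or
  equilibration of real simulations.
- Binary energy files are out of scope; pressure tensors enter as text
  (XVG or delimited tables).
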