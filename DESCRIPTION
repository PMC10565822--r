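Package: gkvisc
Title: Green-Kubo Shear Viscosity Estimation by Time Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the shear (dynamic) viscosity of simulated liquids from
    equilibrium pressure-tensor time series via the Green-Kubo integral, using
    the time-decomposition protocol: per-trajectory running viscosity
    integrals, a power-law fit A*t^b to the inter-trajectory standard
    deviation, and a t^(-b)-weighted multi-exponential fit to the ensemble
    mean whose long-time limit is the viscosity estimate. Includes bootstrap
    convergence diagnostics over trajectory subsets, an Ornstein-Uhlenbeck
    synthetic pressure-fluctuation generator with analytically known
    viscosity for end-to-end validation, readers for GROMACS-style XVG
    pressure output, and a companion rheometry module (cone-plate
    torque-to-viscosity conversion, Ross-Minton concentration-viscosity
    fitting and inversion) for comparing simulation with rotational-rheometry
    measurements of concentrated protein solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
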