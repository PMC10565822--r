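fixture_path <- function() {
  system.file("extdata", "mab_rheometry_297K.tsv", package = "gkvisc")
}

test_that("cone-plate conversion matches the stress / shear-rate oracle", {
  R <- 17.5e-3
  alpha <- pi / 180 # 1 degree
  omega <- 57.3
  # choose M so the shear stress 3M/(2 pi R^3) is 10 Pa
  M <- 10 * 2 * pi * R^3 / 3
  shear_rate <- omega / alpha
  expect_equal(
    cone_plate_viscosity(M, omega, alpha, R),
    10 / shear_rate * 1e3, # Pa.s -> mPa.s
    tolerance = 1e-12
  )
  expect_equal(cone_plate_viscosity(M, omega, alpha, R), 3.05, tolerance = 1e-2)

  expect_equal(cone_plate_viscosity(0, omega, alpha, R), 0)
  expect_equal(
    cone_plate_viscosity(2 * M, omega, alpha, R),
    2 * cone_plate_viscosity(M, omega, alpha, R)
  )
  expect_equal(
    cone_plate_viscosity(M, 2 * omega, alpha, R),
    cone_plate_viscosity(M, omega, alpha, R) / 2
  )
  expect_error(cone_plate_viscosity(M, 0, alpha, R), "angular_velocity")
  expect_error(cone_plate_viscosity(M, omega, 0.5, R), "cone_angle")
  expect_error(cone_plate_viscosity(M, omega, alpha, -1), "cone_radius")
})

test_that("ross_minton_eval limits: rho = 0, zero crowding, singularity", {
  f <- list(eta0 = 1.2, intrinsic_viscosity = 0.008, crowding_ratio = 0.3)
  expect_equal(ross_minton_eval(f, 0), 1.2)

  f0 <- list(eta0 = 1.0, intrinsic_viscosity = 0.01, crowding_ratio = 0)
  rho <- c(10, 50, 150)
  expect_equal(ross_minton_eval(f0, rho), exp(0.01 * rho))

  expect_error(ross_minton_eval(f, 1 / (0.3 * 0.008)), "singularity")
})

test_that("the fitted curve is strictly increasing and log-convex on its domain", {
  f <- list(eta0 = 1.1, intrinsic_viscosity = 0.009, crowding_ratio = 0.35)
  rho <- seq(0, 300, by = 1)
  eta <- ross_minton_eval(f, rho)
  expect_true(all(diff(eta) > 0))
  expect_true(all(diff(diff(log(eta))) > -1e-12))
})

test_that("invert_concentration is the inverse of ross_minton_eval to 1e-10", {
  f <- structure(
    list(eta0 = 1.05, intrinsic_viscosity = 0.0085, crowding_ratio = 0.28),
    class = "ross_minton_fit"
  )
  for (rho0 in c(1, 50, 150, 250, 380)) {
    eta <- ross_minton_eval(f, rho0)
    expect_equal(invert_concentration(f, eta) / rho0, 1, tolerance = 1e-10)
    expect_equal(invert_concentration(f, eta, method = "closed_form") / rho0, 1,
      tolerance = 1e-12
    )
  }
  expect_error(invert_concentration(f, 1.0), "exceed the buffer viscosity")
})

test_that("ross_minton_fit recovers known parameters from noiseless data", {
  truth <- list(eta0 = 1.3, intrinsic_viscosity = 0.0075, crowding_ratio = 0.4)
  rho <- c(20, 60, 100, 140, 180, 220, 260)
  data <- rheo_dataset(rho, ross_minton_eval(truth, rho))
  fit <- ross_minton_fit(data)
  expect_equal(fit$eta0, truth$eta0, tolerance = 1e-3)
  expect_equal(fit$intrinsic_viscosity, truth$intrinsic_viscosity, tolerance = 1e-3)
  expect_equal(fit$crowding_ratio, truth$crowding_ratio, tolerance = 1e-3)
  # generating curve reproduced at every fit point
  expect_equal(ross_minton_eval(fit, rho), data$viscosity, tolerance = 1e-6)

  fixed <- ross_minton_fit(data, eta0_mode = "fixed", eta0_value = 1.3)
  expect_equal(fixed$eta0, 1.3)
  expect_equal(fixed$crowding_ratio, truth$crowding_ratio, tolerance = 1e-3)
})

test_that("fitting requires >= 4 points and keeps duplicate concentrations", {
  expect_error(
    ross_minton_fit(rheo_dataset(c(10, 50, 100), c(1.1, 2, 4))),
    "at least 4"
  )
  d <- read_rheo_table(fixture_path())
  expect_equal(nrow(d), 9)
  expect_equal(sum(d$concentration == 216), 2) # both rows retained
  fit <- ross_minton_fit(d)
  expect_equal(fit$n_points, 9)
})

test_that("the bundled dataset is fitted within a factor 2 at every point", {
  d <- read_rheo_table(fixture_path())
  fit <- ross_minton_fit(d)
  pred <- ross_minton_eval(fit, d$concentration)
  ratio <- pred / d$viscosity
  expect_true(all(ratio > 0.5 & ratio < 2))
  expect_gte(fit$eta0, 0.5)
  expect_lte(fit$eta0, 2.0)
})

test_that("concentration-uncertainty band brackets the central curve", {
  d <- read_rheo_table(fixture_path())
  bb <- concentration_uncertainty_band(d, 0.10)
  rho <- c(50, 120, 200)
  central <- ross_minton_eval(bb$central, rho)
  env <- bb$band(rho)
  expect_true(all(env[, "lower"] <= central + 1e-9))
  expect_true(all(env[, "upper"] >= central - 1e-9))
  # the band is genuinely open at 200 mg/mL
  expect_gt(env[3, "upper"], env[3, "lower"])

  # u = 0 collapses the band onto the central fit
  b0 <- concentration_uncertainty_band(d, 0)
  env0 <- b0$band(rho)
  expect_equal(env0[, "lower"], env0[, "upper"], tolerance = 1e-6)
  expect_error(concentration_uncertainty_band(d, 0.6), "relative_uncertainty")
})

test_that("rheo tables round-trip through delimited text", {
  d <- rheo_dataset(c(50, 100, 150, 200), c(2, 4, 9, 20), c(TRUE, TRUE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  r <- read_rheo_table(path)
  expect_equal(r$concentration, d$concentration)
  expect_equal(r$viscosity, d$viscosity)
  expect_equal(r$filtered, d$filtered)
})
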