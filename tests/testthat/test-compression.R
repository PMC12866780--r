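make_geom_series <- function(time, force, height, radius, H0, R0) {
  mech_series(time, force = force, height = height, radius = radius,
              H0 = H0, R0 = R0)
}

test_that("strain and Cauchy stress follow the printed definitions", {
  s <- make_geom_series(time = 0:2,
                        force = c(0, 0, 1e-3),
                        height = c(3e-3, 2.4e-3, 2.4e-3),
                        radius = c(1.5e-3, 1.5e-3, 1.5e-3),
                        H0 = 3e-3, R0 = 1.5e-3)
  ss <- compute_strain_stress(s)
  # reference state
  expect_equal(ss$eps_rr[1], 0)
  expect_equal(ss$eps_zz[1], 0)
  expect_equal(ss$sigma[1], 0)
  # h_c = 0.8 H0 -> eps_zz = -0.2
  expect_equal(ss$eps_zz[2], -0.2)
  # F = 1 mN over r_c = 1.5 mm: |sigma| = 1e-3 / (pi (1.5e-3)^2), compressive
  expect_equal(ss$sigma[3], -1e-3 / (pi * 1.5e-3^2))
  expect_equal(ss$I_C, ss$lambda_z^2 + 2 * ss$lambda_r^2)
  # non-positive radii can never enter a series
  expect_error(mech_series(0:1, force = c(0, 0), radius = c(1e-3, 0),
                           height = c(1e-3, 1e-3)), "radii")
})

test_that("Poisson ratio is the negative through-origin strain slope", {
  zz <- -c(0.025, 0.05, 0.075, 0.1)
  expect_equal(fit_poisson(data.frame(eps_rr = -0.5 * zz, eps_zz = zz))$nu, 0.5)

  f0 <- fit_poisson(data.frame(eps_rr = 0 * zz, eps_zz = zz))
  expect_identical(f0$nu, 0)
  expect_true(f0$clamped)

  expect_error(fit_poisson(data.frame(eps_rr = c(0, 0), eps_zz = c(0, 0))),
               "axial strain")

  # synthetic relaxation geometry with noiseless radii: nu_true recovered
  # to 10 digits
  g <- gen_relaxation(ref_visco(), nu_true = 0.45, noise_sd = 0, seed = 2)
  ss <- compute_strain_stress(g$series)
  expect_equal(fit_poisson(ss)$nu, 0.45, tolerance = 1e-10)
})

test_that("neo-Hookean fit recovers c exactly from model-generated stresses", {
  lambda_z <- 1 - c(0.025, 0.05, 0.1, 0.15, 0.2)
  c_true <- 500
  sigma <- c_true * (lambda_z^2 - 1 / lambda_z)  # incompressible kinematics
  fit <- fit_neo_hookean(data.frame(lambda_z = lambda_z, sigma = sigma),
                         nu = 0.5, use_measured_lambda_r = FALSE)
  expect_equal(fit$c, 500, tolerance = 1e-12)
  expect_lt(fit$residual, 1e-10)
  expect_equal(fit$E_global, 3 * fit$c)  # E = 2c(1+nu) with nu = 0.5

  # reference state plus one consistent point: zero residual
  two <- data.frame(lambda_z = c(1, 0.9), sigma = c(0, 500 * (0.81 - 1 / 0.9)))
  expect_lt(fit_neo_hookean(two, nu = 0.5, use_measured_lambda_r = FALSE)$residual,
            1e-12)

  expect_error(fit_neo_hookean(data.frame(lambda_z = c(1, 1), sigma = c(0, 0))),
               "lambda_z")
})

test_that("measured-lambda_r and incompressible stress paths coincide at nu = 0.5", {
  lambda_z <- seq(0.8, 1, by = 0.02)
  pts_meas <- data.frame(lambda_z = lambda_z, lambda_r = lambda_z^(-1 / 2),
                         sigma = 400 * (lambda_z^2 - 1 / lambda_z))
  a <- fit_neo_hookean(pts_meas, nu = 0.5, use_measured_lambda_r = TRUE)
  b <- fit_neo_hookean(pts_meas, nu = 0.5, use_measured_lambda_r = FALSE)
  expect_equal(a$c, b$c, tolerance = 1e-12)
  # and both equal the classical incompressible uniaxial curve on the grid
  expect_equal(a$c * (lambda_z^2 - pts_meas$lambda_r^2),
               400 * (lambda_z^2 - 1 / lambda_z), tolerance = 1e-9)
})

test_that("neo-Hookean estimate is linear in the stress scale", {
  lambda_z <- 1 - c(0.05, 0.1, 0.15, 0.2)
  pts <- data.frame(lambda_z = lambda_z,
                    sigma = 300 * (lambda_z^2 - 1 / lambda_z) +
                      c(1, -2, 0.5, 1.5))
  c1 <- fit_neo_hookean(pts, nu = 0.5, use_measured_lambda_r = FALSE)$c
  pts$sigma <- 4 * pts$sigma
  expect_equal(fit_neo_hookean(pts, nu = 0.5,
                               use_measured_lambda_r = FALSE)$c, 4 * c1)
})

test_that("small-strain neo-Hookean modulus matches the linear-elastic slope", {
  # cross-scale consistency: for |eps_zz| <= 1% the hyperelastic E_global
  # agrees with E = sigma/eps within 5%
  c_true <- 500
  eps <- -c(0.002, 0.004, 0.006, 0.008, 0.01)
  lambda_z <- 1 + eps
  sigma <- c_true * (lambda_z^2 - 1 / lambda_z)
  fit <- fit_neo_hookean(data.frame(lambda_z = lambda_z, sigma = sigma),
                         nu = 0.5, use_measured_lambda_r = FALSE)
  E_lin <- sum(sigma * eps) / sum(eps^2)  # through-origin slope oracle
  expect_lt(abs(fit$E_global - E_lin) / E_lin, 0.05)
})

test_that("equilibrium extraction reproduces per-hold strain states", {
  g <- gen_relaxation(ref_visco(), nu_true = 0.5, noise_sd = 0, seed = 4)
  eq <- extract_equilibrium(g$series, compression_protocol())
  expect_equal(eq$eps_zz, -(1:8) * 0.025)
  expect_equal(eq$eps_rr, 0.5 * (1:8) * 0.025)
  expect_true(all(eq$sigma < 0))
})
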