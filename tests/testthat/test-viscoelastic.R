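test_that("equilibrium spring stress follows the exponential-stiffening law", {
  expect_identical(equilibrium_stress(0, 1000, 5), 0)
  expect_equal(equilibrium_stress(0.1, 1000, 0), 100)  # c_b = 0: linear spring
  # direct evaluation oracle
  expect_equal(equilibrium_stress(-0.2, 1000, 5), 1000 * exp(-1) * (-0.2))
})

test_that("hold-phase spring strain matches its closed form and limits", {
  expect_equal(spring_strain(10, 10, 0.05, 500, 150), 0.05)   # t = t_i
  expect_identical(spring_strain(50, 10, 0, 500, 150), 0)     # zero loading
  # domain guard for negative effective strain reports the critical time
  expect_error(spring_strain(1000, 0, -0.05, 500, 150), "critical time")
})

test_that("closed-form spring strain integrates the quadratic dashpot law", {
  skip_if_not_installed("deSolve")
  c_m <- 500; eta <- 150; ehat <- 0.05
  tt <- seq(0, 120, by = 0.5)
  ode <- deSolve::ode(y = c(e = ehat), times = tt,
                      func = function(t, y, p) list(-(c_m / eta) * y[1]^2),
                      rtol = 1e-12, atol = 1e-14)
  closed <- spring_strain(tt, 0, ehat, c_m, eta)
  expect_lt(max(abs(closed - ode[, "e"]) / abs(ode[, "e"])), 1e-8)
})

test_that("protocol simulation has the correct elastic and asymptotic limits", {
  proto <- compression_protocol()
  tt <- seq(0, 960, by = 1)
  # c_m = 0: pure nonlinear spring, stress constant within each hold
  p0 <- visco_params(1000, 2, 0, 150, 1500)
  s0 <- simulate_protocol(p0, proto, tt)
  eps <- (1:8) * 0.025
  sig0 <- equilibrium_stress(eps, 1000, 2)
  idx <- findInterval(tt, (0:7) * 120)
  expect_equal(s0, sig0[idx])

  # single step, t -> infinity: Maxwell contribution decays to sigma_1^0
  p <- ref_visco()
  long <- step_protocol(1, 0.025, 1e6)
  s_inf <- simulate_protocol(p, long, 1e6)
  expect_equal(s_inf, equilibrium_stress(0.025, 1000, 2), tolerance = 1e-3)
})

test_that("stepwise stress equals the componentwise closed-form re-evaluation", {
  # independent oracle: re-derive the per-element carry-over chain in the
  # test and evaluate each Maxwell branch directly
  p <- visco_params(800, 1.5, 300, 100, 900)
  proto <- compression_protocol()
  t_end <- (1:8) * 120 - 1e-6  # just before each next step
  sim <- simulate_protocol(p, proto, t_end)
  eps <- (1:8) * 0.025
  ehat <- matrix(0, 8, 2); carry <- c(0, 0); prev <- 0
  etas <- c(100, 900)
  expected <- numeric(8)
  for (i in 1:8) {
    ehat[i, ] <- eps[i] - prev + carry
    t_i <- (i - 1) * 120
    sp <- etas * ehat[i, ] / (etas + ehat[i, ] * 300 * (t_end[i] - t_i))
    expected[i] <- 800 * exp(1.5 * eps[i]) * eps[i] + 300 * sum(sp)
    carry <- etas * ehat[i, ] / (etas + ehat[i, ] * 300 * 120)
    prev <- eps[i]
  }
  expect_equal(sim, expected, tolerance = 1e-12)
})

test_that("equal viscosities collapse the two Maxwell branches into one mode", {
  p <- visco_params(1000, 2, 500, 400, 400)
  proto <- compression_protocol()
  tt <- seq(0, 960, 0.5)
  s <- simulate_protocol(p, proto, tt)
  # within each hold sigma - sigma_i^0 must be exactly twice a single branch
  st <- mechisto:::.visco_states(p, proto)
  idx <- findInterval(tt, st$t_i)
  one <- vapply(seq_along(tt), function(k) {
    i <- idx[k]
    spring_strain(tt[k], st$t_i[i], st$ehat[i, 1], 500, 400)
  }, numeric(1))
  expect_equal(s - st$sigma0[idx], 2 * 500 * one, tolerance = 1e-12)
})

test_that("stress scales with (c_a, c_m, eta) at fixed strains and times", {
  p <- ref_visco()
  k <- 3.7
  pk <- visco_params(k * p$c_a, p$c_b, k * p$c_m, k * p$eta1, k * p$eta2)
  tt <- seq(0, 960, 7)
  expect_equal(simulate_protocol(pk, compression_protocol(), tt),
               k * simulate_protocol(p, compression_protocol(), tt),
               tolerance = 1e-12)
})

test_that("stress relaxes monotonically toward equilibrium within holds", {
  p <- ref_visco()
  proto <- compression_protocol()
  st <- mechisto:::.visco_states(p, proto)
  for (i in c(1, 4, 8)) {
    tt <- seq(st$t_i[i], st$t_i[i] + 120 - 0.5, 0.5)
    dev <- abs(simulate_protocol(p, proto, tt) - st$sigma0[i])
    expect_true(all(diff(dev) <= 1e-12))
  }
})

test_that("noiseless relaxation records are fitted back to the true parameters", {
  p <- ref_visco()
  g <- gen_relaxation(p, nu_true = 0.45, noise_sd = 0, seed = 3)
  fit <- fit_viscoelastic(g$series, compression_protocol())
  truth <- unlist(p)
  expect_equal(unlist(fit$params), truth, tolerance = 1e-3)  # within 0.1%
  expect_lt(fit$rms, 1e-8)
  expect_false(fit$flags$slow_eta)
})

test_that("the two-step equilibrium stage reproduces pure-equilibrium data", {
  # generator reduced to the nonlinear spring alone (c_m = 0): the fitted
  # (c_a, c_b) must reproduce the end-of-hold stresses exactly
  p0 <- visco_params(1200, 1.2, 0, 150, 1500)
  g <- gen_relaxation(p0, noise_sd = 0, seed = 5)
  fit <- fit_viscoelastic(g$series, compression_protocol(), refine = FALSE)
  eps <- (1:8) * 0.025
  expect_equal(equilibrium_stress(eps, fit$params$c_a, fit$params$c_b),
               equilibrium_stress(eps, 1200, 1.2), tolerance = 1e-6)
})

test_that("a zero-nonlinearity truth is identified as such", {
  # 50 replicates at 1% relative stress noise: the central fitted c_b
  # stays within +/- 0.05 of the true 0
  p <- visco_params(1000, 1e-9, 500, 150, 1500)
  sig_max <- max(simulate_protocol(p, compression_protocol(), seq(0, 960, 1)))
  cb <- vapply(1:50, function(r) {
    g <- gen_relaxation(p, noise_sd = 0.01 * sig_max, seed = 3000 + r)
    fit_viscoelastic(g$series, compression_protocol())$params$c_b
  }, numeric(1))
  expect_lt(abs(median(cb)), 0.05)
  expect_lt(mean(abs(cb) > 0.15), 0.1)
})

test_that("relaxation generator and its degenerate modes are consistent", {
  # noiseless equilibrium: end-of-hold stresses approach the nonlinear
  # spring law when both branches relax fast relative to the hold
  p_fast <- visco_params(1000, 2, 100, 20, 60)
  proto <- step_protocol(8, 0.025, 600)
  g <- gen_relaxation(p_fast, protocol = proto, noise_sd = 0, seed = 6)
  eq <- extract_equilibrium(g$series, proto)
  expect_equal(abs(eq$sigma), equilibrium_stress((1:8) * 0.025, 1000, 2),
               tolerance = 0.01)

  # radius frames satisfy eps_rr = -nu eps_zz exactly
  ss <- compute_strain_stress(g$series)
  expect_equal(ss$eps_rr, -0.45 * ss$eps_zz, tolerance = 1e-12)

  # over-deforming protocols are rejected
  expect_error(gen_relaxation(ref_visco(),
                              protocol = step_protocol(8, 0.13, 10)),
               "100%")
})
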