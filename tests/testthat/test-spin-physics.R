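# Forward models: intensity conversion, CPMG propagators, lineshape
# eigenvalues, spin-lock rates.

test_that("intensity-to-rate conversion matches exponential decay and round-trips", {
  expect_equal(r2eff_from_intensity(1, 1, 0.024), 0)
  expect_equal(r2eff_from_intensity(exp(-1), 1, 0.016), 62.5)
  # -log(0.5) / 0.024 evaluated independently
  expect_equal(r2eff_from_intensity(0.5, 1, 0.024), 28.8811327, tolerance = 1e-7)
  r2 <- c(12.3, 45.6, 150)
  expect_equal(r2eff_from_intensity(intensity_from_r2eff(r2, 2, 0.016), 2, 0.016), r2)
  expect_error(r2eff_from_intensity(-0.1, 1, 0.02), "non-positive intensity")
  expect_error(r2eff_from_intensity(c(1, 0), 1, 0.02, record = c("a", "b")),
               "record b")
})

test_that("SQ propagator equals the Carver-Richards closed form across exchange regimes", {
  acq <- cpmg_acquisition("19F", 500, 0.016,
                          c(62.5, 125, 250, 500, 1000, 2500, 5000))
  for (ratio in c(0.1, 0.5, 2, 10, 100)) {
    for (pG in c(0.6, 0.9)) {
      dw <- 400
      mod <- two_state_exchange(pG, ratio * dw)
      prop <- sq_cpmg_r2eff(mod, dw, 20, acq)
      oracle <- carver_richards(pG, ratio * dw, dw, 20, 20, acq$nu_cpmg)
      expect_lt(max(abs(prop - oracle)), 1e-6)
    }
  }
  # worked case: symmetric populations, 19F shift at 500 MHz
  mod <- two_state_exchange(0.5, 913)
  dw <- ppm_to_rads(0.15, "19F", 500)
  expect_lt(max(abs(sq_cpmg_r2eff(mod, dw, 115, acq) -
                      carver_richards(0.5, 913, dw, 115, 115, acq$nu_cpmg))),
            1e-6)
})

test_that("SQ dispersion limits: no shift difference, fast exchange, monotonicity", {
  acq <- cpmg_acquisition("13C", 600, 0.024, c(83.3, 250, 1000, 2000))
  mod <- two_state_exchange(0.7, 2000)
  expect_equal(sq_cpmg_r2eff(mod, 0, 20, acq), rep(20, 4))

  fastmod <- two_state_exchange(0.9, 1e5)
  rex <- 0.9 * 0.1 * 300^2 / 1e5
  acq100 <- cpmg_acquisition("13C", 600, 0.020, 100)
  expect_equal(sq_cpmg_r2eff(fastmod, 300, 20, acq100, nu = 100),
               20 + rex, tolerance = 0.01)

  # R2_eff non-increasing in nu_cpmg, converging to R2_0
  grid <- cpmg_acquisition("19F", 500, 0.016,
                           c(62.5, 125, 250, 500, 1000, 2500, 5000, 31250))
  for (kex in c(200, 913, 5000)) {
    prof <- sq_cpmg_r2eff(two_state_exchange(0.8, kex), 440, 30, grid)
    expect_true(all(diff(prof) <= 1e-8))
    expect_equal(prof[length(prof)], 30, tolerance = 0.02)
  }
})

test_that("fast-exchange excess broadening scales as pG*pE*dw^2/kex", {
  acq <- cpmg_acquisition("19F", 500, 0.016, c(31.25, 5000))
  for (dw in c(200, 500)) {
    for (pG in c(0.6, 0.85)) {
      kex <- 25 * dw
      prof <- sq_cpmg_r2eff(two_state_exchange(pG, kex), dw, 25, acq)
      rex <- pG * (1 - pG) * dw^2 / kex
      expect_equal(prof[1] - 25, rex, tolerance = 0.05)
    }
  }
})

test_that("MQ propagator reduces to SQ at dw_H = 0 and to R2_0 without shifts", {
  acq <- cpmg_acquisition("13C", 800, 0.024, c(83.3, 250, 1000, 2000),
                          experiment = "MQ")
  mod <- two_state_exchange(0.819, 710)
  dwC <- ppm_to_rads(2, "13C", 800)
  expect_lt(max(abs(mq_cpmg_r2eff(mod, 0, dwC, 18, acq) -
                      sq_cpmg_r2eff(mod, dwC, 18, acq))), 1e-8)
  expect_equal(mq_cpmg_r2eff(mod, 0, 0, 18, acq), rep(18, 4))
})

test_that("MQ propagator matches brute-force small-time-step integration", {
  mod <- two_state_exchange(0.819, 710)
  acq <- cpmg_acquisition("13C", 800, 0.024, 250, experiment = "MQ")
  dwC <- ppm_to_rads(2, "13C", 800)
  dwH <- 2 * pi * 0.1 * 800
  expect_equal(mq_cpmg_r2eff(mod, dwH, dwC, 20, acq, 250),
               brute_mq_cycle_rate(0.819, 710, dwH, dwC, 20, 0.024, 250),
               tolerance = 0.1 / 135)
  expect_equal(mq_cpmg_r2eff(mod, dwH, dwC, 20, acq, 250, detection = "signal"),
               brute_mq_signal(0.819, 710, dwH, dwC, 20, 0.024, 250),
               tolerance = 0.1 / 135)
})

test_that("non-integer pulse counts are rejected", {
  expect_error(cpmg_acquisition("13C", 600, 0.024, c(90)),
               "integer pulse count")
  acq <- cpmg_acquisition("13C", 600, 0.024, c(250))
  mod <- two_state_exchange(0.8, 700)
  expect_error(sq_cpmg_r2eff(mod, 100, 20, acq, nu = 90),
               "integer pulse count")
})

test_that("free-precession eigenvalues give the expected lineshape components", {
  # no exchange: two components at {0, dw} with rates {R2_G, R2_E} and
  # amplitudes {p_GS, p_ES}; use a tiny kex (constructor requires > 0)
  mod0 <- two_state_exchange(0.7, 1e-9)
  ls0 <- free_precession_eigen(mod0, dw = 500, R2_G = 20, R2_E = 40)
  o <- order(ls0$offset)
  expect_equal(ls0$offset[o], c(0, 500), tolerance = 1e-6)
  expect_equal(ls0$R2_obs[o], c(20, 40), tolerance = 1e-6)
  expect_equal(ls0$amplitude[o], c(0.7, 0.3), tolerance = 1e-6)

  # fast exchange: single dominant component at the population average
  modf <- two_state_exchange(0.8, 5e4)
  lsf <- free_precession_eigen(modf, dw = 400, R2_G = 20, R2_E = 20)
  dom <- attr(lsf, "dominant")
  expect_equal(lsf$offset[dom], 0.2 * 400, tolerance = 0.01)
  expect_gt(lsf$amplitude[dom], 0.99)

  # equal intrinsic rates, no shift difference: both real parts equal -R
  lse <- free_precession_eigen(two_state_exchange(0.6, 800), 0, 35, 35)
  expect_equal(sort(lse$R2_obs), c(35, 35 + 800), tolerance = 1e-9)

  # amplitudes always sum to 1; decay rates positive
  for (kex in c(50, 913, 2e4)) {
    ls <- free_precession_eigen(two_state_exchange(0.55, kex), 440, 115, 115)
    expect_equal(sum(ls$amplitude), 1, tolerance = 1e-10)
    expect_true(all(ls$R2_obs > 0))
    expect_true(all(ls$fwhm > 0))
  }
})

test_that("spin-lock rates: on-resonance limits and fast-exchange closed form", {
  sl <- r1rho_acquisition(500, c(0, 4, 8, 16, 32) / 1000,
                          c(50, 100, 500, 2000, 8000))
  mod <- two_state_exchange(0.9, 1000)
  expect_equal(r1rho_onres(mod, 0, 20, 2, sl), rep(20, 5), tolerance = 1e-8)

  # strong lock quenches exchange
  expect_equal(r1rho_onres(two_state_exchange(0.5, 913),
                           ppm_to_rads(0.15, "19F", 500), 115, 2, sl,
                           nu_SL = 8000),
               115, tolerance = 0.02)

  # fast exchange: R2_0 + pG*pE*dw^2*kex / (kex^2 + w1^2)
  fastmod <- two_state_exchange(0.9, 1e5)
  for (nu in c(100, 1000, 8000)) {
    cf <- 20 + 0.9 * 0.1 * 300^2 * 1e5 / (1e5^2 + (2 * pi * nu)^2)
    expect_equal(r1rho_onres(fastmod, 300, 20, 2, sl, nu_SL = nu), cf,
                 tolerance = 0.01)
  }
})

test_that("spin-lock eigenvalue fast path agrees with propagation plus fit", {
  grids <- list(
    c(50, 75, 100, 125, 150, 200, 250, 300, 400, 500, 600, 700, 800,
      1000, 2500, 3000, 5000, 8000),
    c(50, 75, 100, 125, 150, 200, 250, 300, 400, 500, 600, 800, 1000,
      1500, 2000, 3000, 5000, 8000))
  fields <- c(500, 600)
  mod <- two_state_exchange(0.5, 913)
  for (i in 1:2) {
    sl <- r1rho_acquisition(fields[i], c(0, 4, 8, 16, 32) / 1000, grids[[i]])
    dw <- ppm_to_rads(0.15, "19F", fields[i])
    a <- r1rho_onres(mod, dw, 115, 2, sl)
    b <- r1rho_onres(mod, dw, 115, 2, sl, method = "propagation")
    expect_lt(max(abs(a - b) / a), 0.01)
  }
})
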