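# Single-site anisotropy binding and catalytic turnover.

test_that("anisotropy model limits: free ligand, saturation, monotonicity", {
  expect_equal(anisotropy_model(0, RNA = 1, K_D = 10, r_min = 0.05, s = 0.2),
               0.05)
  # [P] -> Inf saturates the complex at [RNA]
  expect_equal(anisotropy_model(1e9, RNA = 1, K_D = 10, r_min = 0.05, s = 0.2),
               0.05 + 0.2 * 1, tolerance = 1e-6)
  P <- seq(0, 2000, by = 5)
  r <- anisotropy_model(P, RNA = 1, K_D = 25, r_min = 0.05, s = 0.2)
  expect_true(all(diff(r) >= 0))
})

test_that("noiseless titrations are recovered exactly across the affinity range", {
  for (kd in c(1, 10, 100, 1000)) {
    cur <- simulate_titration(K_D = kd, RNA_conc = 1, noise = 0, seed = 1)
    fit <- anisotropy_fit(cur)
    expect_equal(fit$K_D, kd, tolerance = 1e-4)
    expect_equal(fit$r_min, 0.05, tolerance = 1e-6)
    expect_equal(fit$s, 0.15, tolerance = 1e-4)
  }
})

test_that("replicated noisy titrations recover K_D with replicate-based errors", {
  kds <- vapply(1:100, function(r) {
    cur <- simulate_titration(K_D = 10, RNA_conc = 1, noise = 0.02,
                              replicates = 3, seed = r)
    anisotropy_fit(cur)$K_D
  }, 0)
  expect_lt(abs(median(kds) - 10) / 10, 0.2)
  cur <- simulate_titration(K_D = 10, RNA_conc = 1, noise = 0.02,
                            replicates = 3, seed = 1)
  fit <- anisotropy_fit(cur)
  expect_equal(nrow(fit$per_replicate), 3)
  expect_gt(fit$K_D_se, 0)
})

test_that("a zero-protein grid gives a flat curve at r_min and no fit", {
  cur <- simulate_titration(K_D = 10, RNA_conc = 1, P_grid = 0, noise = 0,
                            seed = 1)
  expect_equal(cur$r_obs, 0.05)
  expect_error(anisotropy_fit(cur), "at least 5 distinct")
})

test_that("turnover rate comes from the product-fraction slope", {
  # product grows at 2.5 uM/min with E0 = 50 uM, S0 = 500 uM
  t <- seq(0, 50, by = 5)
  ser <- data.frame(time = t, product_signal = 2.5 * t,
                    substrate_signal = 500 - 2.5 * t)
  expect_equal(turnover_rate(ser, E0 = 50, S0 = 500)$rate, 0.05,
               tolerance = 1e-10)
  flat <- data.frame(time = t, product_signal = rep(1e-3, 11),
                     substrate_signal = rep(500, 11))
  expect_equal(turnover_rate(flat, E0 = 50, S0 = 500)$rate, 0)
})

test_that("turnover rate is invariant to the intensity unit", {
  ser <- simulate_turnover(rate = 0.05, noise = 0.02, seed = 42)
  r1 <- turnover_rate(ser)
  ser2 <- ser
  ser2$product_signal <- ser2$product_signal * 7.3e4
  ser2$substrate_signal <- ser2$substrate_signal * 7.3e4
  attr(ser2, "E0") <- attr(ser, "E0")
  attr(ser2, "S0") <- attr(ser, "S0")
  expect_equal(turnover_rate(ser2)$rate, r1$rate, tolerance = 1e-12)
})

test_that("noisy turnover series recover the generating rate", {
  rates <- vapply(1:100, function(r)
    turnover_rate(simulate_turnover(rate = 0.05, noise = 0.02,
                                    seed = r))$rate, 0)
  expect_lt(abs(median(rates) - 0.05) / 0.05, 0.1)
})

test_that("out-of-window and degenerate series are flagged", {
  t <- seq(100, 200, by = 10) # deep conversion from the first point on
  ser <- data.frame(time = t, product_signal = pmin(2.5 * t, 499),
                    substrate_signal = pmax(500 - 2.5 * t, 1))
  expect_warning(turnover_rate(ser, E0 = 50, S0 = 500), "conversion")
  expect_error(turnover_rate(data.frame(time = c(1, 1, 2),
                                        product_signal = 1:3,
                                        substrate_signal = 3:1),
                             E0 = 1, S0 = 1), "strictly increasing")
})

test_that("relative rates divide out shared conditions", {
  ser <- simulate_turnover(rate = 0.05, noise = 0, seed = 1)
  expect_equal(relative_rate(ser, ser)$ratio, 1)
  sa <- data.frame(time = 0:10, product_signal = 2.5 * (0:10),
                   substrate_signal = 500 - 2.5 * (0:10))
  sb <- data.frame(time = 0:10, product_signal = 1.25 * (0:10),
                   substrate_signal = 500 - 1.25 * (0:10))
  expect_equal(relative_rate(sa, sb, E0 = 50, S0 = 500)$ratio, 2,
               tolerance = 1e-10)
  flat <- data.frame(time = 0:10, product_signal = rep(0, 11),
                     substrate_signal = rep(500, 11))
  expect_error(relative_rate(sa, flat, E0 = 50, S0 = 500), "not positive")
  # stochastic recovery of a WT/mutant ratio
  ratios <- vapply(1:100, function(r) {
    wt <- simulate_turnover(rate = 0.056, noise = 0.02, seed = 2 * r)
    mut <- simulate_turnover(rate = 0.04, noise = 0.02, seed = 2 * r + 1)
    relative_rate(wt, mut)$ratio
  }, 0)
  expect_lt(abs(median(ratios) - 1.4) / 1.4, 0.15)
})
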