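# Global fitting: sigma floors, self-consistency, parameter sharing,
# Monte Carlo errors and chi-square surfaces.

make_noiseless_profiles <- function(p_GS = 0.8, k_ex = 800, dw_ppm = 0.2,
                                    R2_0 = 100, sigma = 1,
                                    fields = c(500, 600)) {
  lapply(fields, function(f) {
    acq <- cpmg_acquisition("19F", f, 0.016,
                            c(62.5, 125, 187.5, 250, 375, 500, 1000,
                              2500, 5000))
    vals <- sq_cpmg_r2eff(two_state_exchange(p_GS, k_ex),
                          ppm_to_rads(dw_ppm, "19F", f), R2_0, acq)
    dispersion_profile("F1", "19F", f, 313, "SQ",
                       data.frame(nu_Hz = acq$nu_cpmg, value = vals,
                                  sigma = sigma),
                       T_CPMG = 0.016)
  })
}

chi2_at <- function(theta, profiles, schema) {
  model <- rdfit:::model_values(theta, profiles, schema)
  sum(unlist(lapply(seq_along(profiles), function(i)
    ((profiles[[i]]$points$value - model[[i]]) /
       profiles[[i]]$points$sigma)^2)))
}

test_that("sigma floors replace small and missing uncertainties only", {
  pts <- data.frame(nu_Hz = c(62.5, 125, 250, 500),
                    value = c(150, 140, 130, 120),
                    sigma = c(0.05, 5, 1.9, NA))
  p13 <- dispersion_profile("P1", "13C", 600, 313, "SQ", pts, T_CPMG = 0.024)
  expect_equal(apply_sigma_floor(p13)$points$sigma, c(0.2, 5, 1.9, 0.2))
  expect_equal(apply_sigma_floor(p13, floor = 0.2)$points$sigma[1], 0.2)
  p19 <- dispersion_profile("P1", "19F", 600, 313, "SQ", pts, T_CPMG = 0.016)
  expect_equal(apply_sigma_floor(p19)$points$sigma, c(2, 5, 2, 2))
})

test_that("replicates aggregate to mean and standard deviation", {
  df <- data.frame(nu_Hz = rep(c(62.5, 125), each = 2),
                   value = c(10, 12, 8, 9))
  agg <- aggregate_replicates(df)
  expect_equal(agg$value, c(11, 8.5))
  expect_equal(agg$sigma, c(sd(c(10, 12)), sd(c(8, 9))))
  expect_equal(agg$n_rep, c(2L, 2L))
})

test_that("noiseless data initialized at truth are recovered exactly", {
  profs <- make_noiseless_profiles()
  schema <- fit_schema(profs,
                       starts = data.frame(p_GS = 0.8, k_ex = 800))
  fit <- fit_global(profs, schema)
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$par[["pGS"]], 0.8, tolerance = 1e-4)
  expect_equal(fit$par[["kex"]], 800, tolerance = 1e-4)
  expect_equal(fit$par[["dw.F1"]], 0.2, tolerance = 1e-4)
})

test_that("noiseless data are recovered from the generic multi-start grid", {
  profs <- make_noiseless_profiles(sigma = 0.5)
  fit <- fit_global(profs)
  expect_equal(fit$par[["kex"]], 800, tolerance = 1e-3)
  expect_equal(fit$par[["dw.F1"]], 0.2, tolerance = 1e-3)
})

test_that("chi2 is invariant under profile and point reordering", {
  profs <- make_noiseless_profiles(sigma = 2)
  n1 <- nrow(profs[[1]]$points)
  profs[[1]]$points$value <- profs[[1]]$points$value +
    rep_len(c(1, -1), n1)
  schema <- fit_schema(profs)
  theta <- rdfit:::schema_init(schema, profs, 0.8, 900)
  rev_profs <- rev(profs)
  rev_schema <- fit_schema(rev_profs)
  expect_equal(chi2_at(theta, profs, schema),
               chi2_at(theta[rev_schema$params$name], rev_profs, rev_schema))
  shuffled <- profs
  o <- c(5, 3, 9, 1, 2, 8, 4, 7, 6)
  shuffled[[1]]$points <- shuffled[[1]]$points[o, ]
  expect_equal(chi2_at(theta, profs, schema),
               chi2_at(theta, shuffled, schema))
})

test_that("duplicating a profile doubles its chi2 block at fixed parameters", {
  profs <- make_noiseless_profiles(sigma = 2)
  profs[[1]]$points$value <- profs[[1]]$points$value + 1 # offset -> chi2 > 0
  schema1 <- fit_schema(profs[1])
  theta <- rdfit:::schema_init(schema1, profs[1], 0.8, 900)
  c1 <- chi2_at(theta, profs[1], schema1)
  dup <- list(profs[[1]], profs[[1]])
  schema2 <- fit_schema(dup)
  expect_equal(chi2_at(theta, dup, schema2), 2 * c1)
})

test_that("a flat profile leaves exchange unidentifiable and is flagged", {
  acq <- cpmg_acquisition("19F", 500, 0.016, c(62.5, 125, 250, 500, 1000))
  vals <- rep(100, 5)
  prof <- dispersion_profile("F1", "19F", 500, 313, "SQ",
                             data.frame(nu_Hz = acq$nu_cpmg, value = vals,
                                        sigma = 2),
                             T_CPMG = 0.016)
  expect_warning(fit <- fit_global(list(prof)), "box constraint")
  expect_true(length(fit$boundary) >= 1)
  expect_lt(fit$chi2, 1e-10)
})

test_that("fitting rejects profiles without usable uncertainties", {
  profs <- make_noiseless_profiles()
  profs[[1]]$points$sigma[2] <- NA
  expect_error(fit_global(profs), "apply_sigma_floor")
})

test_that("single-temperature series fit reduces to the global fit", {
  profs <- make_noiseless_profiles(sigma = 0.5)
  f1 <- fit_global(profs, fit_schema(profs,
                                     starts = data.frame(p_GS = 0.7,
                                                         k_ex = 1000)))
  f2 <- fit_temperature_series(profs,
                               starts = data.frame(p_GS = 0.7, k_ex = 1000))
  expect_equal(f1$par, f2$par, tolerance = 1e-8)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-8)
})

test_that("joint nuclei fit with one empty list reduces to a global fit", {
  profs <- make_noiseless_profiles(sigma = 0.5)
  fj <- fit_joint_nuclei(profs, list())
  fg <- fit_global(profs)
  expect_equal(fj$par, fg$par, tolerance = 1e-10)
  fj2 <- fit_joint_nuclei(list(), profs)
  expect_equal(fj2$par, fg$par, tolerance = 1e-10)
})

test_that("conflicting exchange regimes inflate the joint reduced chi2", {
  profs_a <- make_noiseless_profiles(k_ex = 500, dw_ppm = 0.25,
                                     sigma = 0.5, fields = 500)
  profs_b <- lapply(make_noiseless_profiles(k_ex = 2000, dw_ppm = 0.25,
                                            sigma = 0.5, fields = 600),
                    function(p) { p$probe_id <- "F2"; p })
  fa <- fit_global(profs_a)
  fb <- fit_global(profs_b)
  # shared exchange parameters across incompatible generators
  joint <- suppressWarnings(fit_global(c(profs_a, profs_b)))
  expect_gt(joint$chi2nu, 10 * max(fa$chi2nu, fb$chi2nu) + 1)
})

test_that("Monte Carlo errors vanish with vanishing uncertainties", {
  profs <- make_noiseless_profiles(sigma = 1e-9)
  schema <- fit_schema(profs, starts = data.frame(p_GS = 0.8, k_ex = 800))
  fit <- fit_global(profs, schema)
  mc <- monte_carlo_errors(fit, profs, n_cycles = 5, seed = 1)
  expect_lt(max(mc$sd), 1e-6)
})

test_that("Monte Carlo errors are seed-reproducible and seed-stable", {
  fx <- fixture_f19_single(seed = 11)
  profs <- simulate_fixture(fx)
  fit <- suppressWarnings(fit_global(profs))
  mc1 <- monte_carlo_errors(fit, profs, n_cycles = 40, seed = 5)
  mc1b <- monte_carlo_errors(fit, profs, n_cycles = 40, seed = 5)
  expect_identical(mc1$sd, mc1b$sd)
  mc2 <- monte_carlo_errors(fit, profs, n_cycles = 40, seed = 6)
  key <- c("kex", "dw.F12")
  expect_lt(max(abs(mc1$sd[key] - mc2$sd[key]) /
                  pmax(mc1$sd[key], mc2$sd[key])), 0.3)
})

test_that("chi2 surfaces are consistent with the unconstrained optimum", {
  profs <- make_noiseless_profiles(sigma = 0.5)
  schema <- fit_schema(profs, starts = data.frame(p_GS = 0.8, k_ex = 800))
  fit <- fit_global(profs, schema)

  grid <- c(600, 700, 800, 900, 1000)
  surf <- chi2_surface(fit, profs, "kex", grid)
  expect_true(all(surf$converged))
  expect_equal(surf$value[which.min(surf$chi2nu)], 800)
  expect_lt(min(surf$chi2nu), 1e-8)
  # surface containing the best-fit value reproduces the unconstrained chi2nu
  surf2 <- chi2_surface(fit, profs, "kex",
                        c(fit$par[["kex"]], fit$par[["kex"]] * 1.05))
  expect_lt(abs(min(surf2$chi2nu) - fit$chi2nu), 1e-6)

  # grid excluding the minimum decreases monotonically toward the near edge
  surf3 <- chi2_surface(fit, profs, "kex", c(1200, 1500, 2000, 3000))
  expect_true(all(diff(surf3$chi2nu) > 0))
})

test_that("Monte Carlo spread matches the profile-likelihood interval", {
  fx <- fixture_f19_single(seed = 11)
  profs <- simulate_fixture(fx)
  fit <- suppressWarnings(
    fit_global(profs, fit_schema(profs,
                                 starts = data.frame(p_GS = 0.7,
                                                     k_ex = 1000))))
  mc <- monte_carlo_errors(fit, profs, n_cycles = 60, seed = 2)
  k0 <- fit$par[["kex"]]
  grid <- k0 + seq(-80, 80, by = 20)
  surf <- chi2_surface(fit, profs, "kex", grid)
  dof <- fit$n_points - fit$n_free
  target <- min(surf$chi2nu) + 1 / dof
  f <- stats::approxfun(surf$value, surf$chi2nu)
  lo <- stats::uniroot(function(x) f(x) - target, c(min(grid), k0))$root
  hi <- stats::uniroot(function(x) f(x) - target, c(k0, max(grid)))$root
  half <- (hi - lo) / 2
  expect_gt(mc$sd[["kex"]] / half, 0.5)
  expect_lt(mc$sd[["kex"]] / half, 2)
})

test_that("recovery and Monte Carlo coverage behave across stochastic replicates", {
  # stochastic study on the single-temperature fluorine fixture; sigma
  # flooring makes the Monte Carlo intervals conservative, so coverage
  # sits at the top of the expected band
  n_rep <- 100
  truth_kex <- 913
  kex_hat <- numeric(n_rep)
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    fx <- fixture_f19_single(seed = 100 + r)
    profs <- simulate_fixture(fx)
    fit <- suppressWarnings(
      fit_global(profs, fit_schema(profs,
                                   starts = data.frame(p_GS = 0.7,
                                                       k_ex = 1000))))
    mc <- suppressWarnings(
      monte_carlo_errors(fit, profs, n_cycles = 60, seed = r))
    kex_hat[r] <- fit$par[["kex"]]
    covered[r] <- abs(kex_hat[r] - truth_kex) <= mc$sd[["kex"]]
  }
  expect_lt(abs(median(kex_hat) - truth_kex) / truth_kex, 0.05)
  expect_gte(mean(covered), 0.55)
  expect_lte(mean(covered), 0.85)
})
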