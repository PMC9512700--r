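# Synthetic-data generator: fixtures encode complete acquisition schemes
# and ground-truth parameters so that every analysis stage can be
# exercised and validated without measured spectra.  Fixture truths for
# probe-level quantities that are not published (per-probe shift
# differences, intrinsic rates) are explicit stand-ins, chosen once and
# recorded here.

# printed CPMG frequency grids (Hz)
.grid_c13_cpmg <- c(83.3, 166.7, 250, 333.3, 416.7, 500, 666.7, 833.3,
                    1000, 1166.7, 1333.3, 1666.7, 2000)
.grid_f19_cpmg_500 <- c(62.5, 125, 187.5, 250, 312.5, 375, 437.5, 500,
                        562.5, 1000, 1500, 2500, 5000)
.grid_f19_cpmg_600 <- c(62.5, 125, 187.5, 250, 312.5, 375, 437.5, 500,
                        625, 1000, 1500, 2000, 2500, 3000, 3500, 4000,
                        4500, 5000)
.grid_f19_sl_500 <- c(50, 75, 100, 125, 150, 200, 250, 300, 400, 500,
                      600, 700, 800, 1000, 2500, 3000, 5000, 8000)
.grid_f19_sl_600 <- c(50, 75, 100, 125, 150, 200, 250, 300, 400, 500,
                      600, 800, 1000, 1500, 2000, 3000, 5000, 8000)
.tsl_f19 <- c(0, 4, 8, 16, 32) / 1000

#' Synthetic-data fixture
#'
#' Bundles ground-truth exchange parameters, probe parameters, an
#' acquisition set, a noise model and a seed.  Regeneration from the same
#' fixture (same seed) is bit-identical.
#'
#' @param name fixture label.
#' @param exchange named list mapping temperature keys (e.g. `"313"`) to
#'   [two_state_exchange()] truths.
#' @param probes list of [probe_params()] truths.
#' @param cpmg list of [cpmg_acquisition()] objects.
#' @param r1rho list of [r1rho_acquisition()] objects.
#' @param noise_intensity relative Gaussian intensity noise (one value, or
#'   named per experiment class `cpmg` / `r1rho`).
#' @param replicates number of replicate acquisitions.
#' @param seed integer seed used when simulating.
#' @return An object of class `rd_fixture`.
#' @seealso [fixture_c13_313K()], [fixture_f19_multiT()],
#'   [fixture_f19_single()]
#' @export
rd_fixture <- function(name, exchange, probes, cpmg = list(),
                       r1rho = list(), noise_intensity = 0.005,
                       replicates = 2, seed = 1L) {
  stopifnot(length(exchange) >= 1,
            all(vapply(exchange, inherits, TRUE, "two_state_exchange")))
  structure(list(name = name, exchange = exchange, probes = probes,
                 cpmg = cpmg, r1rho = r1rho,
                 noise_intensity = noise_intensity,
                 replicates = replicates, seed = as.integer(seed)),
            class = "rd_fixture")
}

#' @export
print.rd_fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s': %d probes, %d CPMG + %d R1rho acquisitions, %d temperature(s), seed %d\n",
              x$name, length(x$probes), length(x$cpmg), length(x$r1rho),
              length(x$exchange), x$seed))
  invisible(x)
}

noise_of <- function(fixture, kind) {
  n <- fixture$noise_intensity
  if (!is.null(names(n)) && kind %in% names(n)) unname(n[[kind]]) else
    unname(n[[1]])
}

#' Methyl SQ+MQ CPMG fixture at 313 K
#'
#' Five isoleucine-like 13C methyl probes measured by SQ and MQ CPMG at
#' 500, 600 and 800 MHz proton frequency (six dataset blocks) with
#' `T_CPMG = 24` ms and the standard 13-point frequency grid, generated
#' at the exchange truth `p_ES = 0.181`, `k_ex = 710` 1/s.  Per-probe
#' carbon shift differences (1-3 ppm), proton shift differences
#' (0-0.2 ppm) and field-dependent intrinsic rates are fixed stand-in
#' values recorded in the fixture.  Intensity noise is calibrated so the
#' replicate scatter of `R2_eff` is near 0.2 1/s; acquisitions are
#' duplicated.
#'
#' @param seed simulation seed.
#' @return An `rd_fixture`.
#' @export
fixture_c13_313K <- function(seed = 1L) {
  probes <- Map(function(id, dwc, dwh)
    probe_params(id, delta_omega_X = dwc, delta_omega_H = dwh),
    c("P1", "P2", "P3", "P4", "P5"),
    c(1.40, 2.70, 1.90, 2.30, 1.10),
    c(0.05, 0.12, 0.02, 0.18, 0.08))
  fields <- c(500, 600, 800)
  r2_sq <- c(`500` = 18, `600` = 21, `800` = 26)
  r2_mq <- c(`500` = 15, `600` = 17, `800` = 21)
  cpmg <- list()
  for (f in fields) for (exp in c("SQ", "MQ")) {
    acq <- cpmg_acquisition("13C", f, T_CPMG = 0.024,
                            nu_cpmg = .grid_c13_cpmg, experiment = exp,
                            temperature_K = 313)
    acq$R2_0 <- if (exp == "SQ") r2_sq[[as.character(f)]] else
      r2_mq[[as.character(f)]]
    cpmg <- c(cpmg, list(acq))
  }
  rd_fixture("c13_313K",
             exchange = list(`313` = two_state_exchange(1 - 0.181, 710)),
             probes = probes, cpmg = cpmg,
             noise_intensity = c(cpmg = 0.2 * 0.024),
             replicates = 2, seed = seed)
}

#' Fluorine CPMG + R1rho multi-temperature fixture
#'
#' One surface fluorine probe measured by CPMG (`T_CPMG = 16` ms) and
#' on-resonance spin lock at 500 and 600 MHz proton frequency and five
#' temperatures from 303 K to 313 K, using the printed frequency and
#' spin-lock grids.  The exchange truth holds `p_GS = 0.50` at all
#' temperatures and interpolates `k_ex` linearly from 445 1/s (303 K) to
#' 913 1/s (313 K); `|dw| = 0.15` ppm is temperature independent.  The
#' intrinsic rate `R2_0 = 115` 1/s reproduces an observed apo linewidth
#' of about 55 Hz at 500 MHz and 313 K, and `R1 = 2` 1/s.  Intensity
#' noise is calibrated so the replicate scatter of both `R2_eff` and
#' `R1rho` sits near the 2 1/s floor (CPMG: relative intensity noise
#' `2 * T_CPMG`; spin lock: 0.05, which propagates to a rate scatter of
#' about 2 1/s through the exponential fit over the five spin-lock
#' times); acquisitions are triplicated.
#'
#' @param seed simulation seed.
#' @param temperatures temperatures in kelvin.
#' @return An `rd_fixture`.
#' @export
fixture_f19_multiT <- function(seed = 1L,
                               temperatures = c(303, 305.5, 308,
                                                310.5, 313)) {
  probes <- list(probe_params("F12", delta_omega_X = 0.15,
                              R2_0 = 115, R1 = 2))
  exchange <- lapply(temperatures, function(Tk)
    two_state_exchange(0.50, 445 + (913 - 445) * (Tk - 303) / 10))
  names(exchange) <- as.character(temperatures)
  cpmg <- list()
  r1rho <- list()
  for (Tk in temperatures) {
    for (f in c(500, 600)) {
      grid <- if (f == 500) .grid_f19_cpmg_500 else .grid_f19_cpmg_600
      acq <- cpmg_acquisition("19F", f, T_CPMG = 0.016, nu_cpmg = grid,
                              experiment = "SQ", temperature_K = Tk)
      acq$R2_0 <- 115
      cpmg <- c(cpmg, list(acq))
      slg <- if (f == 500) .grid_f19_sl_500 else .grid_f19_sl_600
      sl <- r1rho_acquisition(f, T_SL = .tsl_f19, nu_SL = slg,
                              nucleus = "19F", temperature_K = Tk)
      sl$R2_0 <- 115
      r1rho <- c(r1rho, list(sl))
    }
  }
  rd_fixture("f19_multiT", exchange = exchange, probes = probes,
             cpmg = cpmg, r1rho = r1rho,
             noise_intensity = c(cpmg = 2 * 0.016, r1rho = 0.05),
             replicates = 3, seed = seed)
}

#' Reduced single-temperature fluorine fixture
#'
#' The 313 K slice of [fixture_f19_multiT()]; convenient for fast
#' recovery studies.
#'
#' @param seed simulation seed.
#' @return An `rd_fixture`.
#' @export
fixture_f19_single <- function(seed = 1L) {
  fx <- fixture_f19_multiT(seed = seed, temperatures = 313)
  fx$name <- "f19_313K"
  fx
}

simulate_one_cpmg <- function(fixture, acq, probe, model, rep_id) {
  dw <- ppm_to_rads(probe$delta_omega_X, acq$nucleus, acq$field_MHz)
  r2eff <- if (acq$experiment == "SQ") {
    cpp_sq_cpmg(model$p_GS, model$k_ex, dw, acq$R2_0, acq$R2_0,
                acq$T_CPMG, acq$nu_cpmg, 0L)
  } else {
    dwh <- 2 * pi * probe$delta_omega_H * acq$field_MHz
    cpp_mq_cpmg(model$p_GS, model$k_ex, dwh, dw, acq$R2_0,
                acq$T_CPMG, acq$nu_cpmg, 0L)
  }
  I0 <- 1
  mean_int <- intensity_from_r2eff(r2eff, I0, acq$T_CPMG)
  f <- noise_of(fixture, "cpmg")
  if (any(mean_int - 4 * f * mean_int < 0))
    stop("fixture error: noise level implies negative mean intensities")
  int <- mean_int * (1 + rnorm(length(mean_int), 0, f))
  data.frame(probe_id = probe$probe_id, nucleus = acq$nucleus,
             field_MHz = acq$field_MHz,
             temperature_K = acq$temperature_K,
             experiment = acq$experiment, nu_Hz = acq$nu_cpmg,
             T_relax_s = acq$T_CPMG, replicate = rep_id,
             intensity = int, I0 = I0)
}

#' Simulate constant-time CPMG intensity data from a fixture
#'
#' For every probe, acquisition block and replicate of the fixture the
#' generator evaluates the forward model, converts `R2_eff` to intensities
#' `I(nu) = I_0 * exp(-R2_eff * T_CPMG)` and applies multiplicative
#' Gaussian intensity noise; replicates are drawn independently.  Output
#' includes the intensity-level table, the per-replicate rate table and
#' aggregated, sigma-floored [dispersion_profile()]s ready for fitting.
#'
#' @param fixture an `rd_fixture` with CPMG acquisitions.
#' @param seed overrides the fixture seed.
#' @return List with `intensities` (data frame), `rates` (data frame) and
#'   `profiles` (list of [dispersion_profile()]).
#' @export
simulate_cpmg <- function(fixture, seed = fixture$seed) {
  stopifnot(inherits(fixture, "rd_fixture"), length(fixture$cpmg) > 0)
  tabs <- with_seed(seed, {
    out <- list()
    for (acq in fixture$cpmg) {
      model <- fixture_model(fixture, acq$temperature_K)
      for (probe in fixture$probes)
        for (r in seq_len(fixture$replicates))
          out <- c(out, list(simulate_one_cpmg(fixture, acq, probe,
                                               model, r)))
    }
    out
  })
  intensities <- do.call(rbind, tabs)
  rates <- intensities
  rates$value <- mapply(r2eff_from_intensity, rates$intensity, rates$I0,
                        rates$T_relax_s)
  profiles <- build_profiles(rates)
  list(intensities = intensities, rates = rates, profiles = profiles)
}

fixture_model <- function(fixture, temperature_K) {
  key <- as.character(temperature_K)
  m <- fixture$exchange[[key]]
  if (is.null(m)) stop("fixture has no exchange truth at ", key, " K")
  m
}

build_profiles <- function(rates) {
  groups <- split(rates, interaction(rates$probe_id, rates$field_MHz,
                                     rates$temperature_K,
                                     rates$experiment, drop = TRUE))
  profiles <- lapply(groups, function(g) {
    pts <- aggregate_replicates(g)
    p <- dispersion_profile(g$probe_id[1], g$nucleus[1], g$field_MHz[1],
                            g$temperature_K[1], g$experiment[1], pts,
                            T_CPMG = if (g$experiment[1] != "R1rho")
                              g$T_relax_s[1] else NULL,
                            T_SL = attr(rates, "T_SL") %||%
                              c(0, 0.004, 0.008, 0.016, 0.032))
    apply_sigma_floor(p)
  })
  names(profiles) <- NULL
  profiles
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate spin-lock decay data from a fixture
#'
#' For every spin-lock field the signal decays mono-exponentially over
#' the spin-lock times at the model rate `R1rho(nu_SL)` (the rotating-
#' frame rate returned by [r1rho_onres()]), with multiplicative Gaussian
#' intensity noise per `(nu_SL, T_SL)` point; `R1rho` is then extracted
#' per replicate by a log-linear exponential fit over `T_SL`, replicates
#' are aggregated and sigma floors applied.
#'
#' @inheritParams simulate_cpmg
#' @return List with `intensities` (per `(nu_SL, T_SL)` signals), `rates`
#'   (per-replicate `R1rho`) and `profiles`.
#' @export
simulate_r1rho <- function(fixture, seed = fixture$seed) {
  stopifnot(inherits(fixture, "rd_fixture"), length(fixture$r1rho) > 0)
  f <- noise_of(fixture, "r1rho")
  res <- with_seed(seed, {
    ints <- list()
    rts <- list()
    for (acq in fixture$r1rho) {
      model <- fixture_model(fixture, acq$temperature_K)
      for (probe in fixture$probes) {
        dw <- ppm_to_rads(probe$delta_omega_X, acq$nucleus, acq$field_MHz)
        r1rho_true <- cpp_r1rho(model$p_GS, model$k_ex, dw, acq$R2_0,
                                probe$R1, acq$nu_SL, 0L, acq$T_SL,
                                0, TRUE)
        decay <- exp(-outer(r1rho_true, acq$T_SL))
        for (r in seq_len(fixture$replicates)) {
          obs <- decay * (1 + matrix(rnorm(length(decay), 0, f),
                                     nrow(decay)))
          if (any(obs <= 0))
            stop("fixture error: noise level implies non-positive signals")
          tfit <- acq$T_SL
          if (length(tfit) < 2 || all(tfit == 0))
            stop("fixture error: no decay information in T_SL grid")
          r1rho <- vapply(seq_along(acq$nu_SL), function(i) {
            unname(-coef(lm(log(obs[i, ]) ~ tfit))[2])
          }, 0)
          ints <- c(ints, list(data.frame(
            probe_id = probe$probe_id, nucleus = acq$nucleus,
            field_MHz = acq$field_MHz,
            temperature_K = acq$temperature_K, experiment = "R1rho",
            nu_Hz = rep(acq$nu_SL, times = length(tfit)),
            T_SL_s = rep(tfit, each = length(acq$nu_SL)),
            replicate = r, intensity = as.vector(obs))))
          rts <- c(rts, list(data.frame(
            probe_id = probe$probe_id, nucleus = acq$nucleus,
            field_MHz = acq$field_MHz,
            temperature_K = acq$temperature_K, experiment = "R1rho",
            nu_Hz = acq$nu_SL, T_relax_s = NA_real_, replicate = r,
            value = r1rho)))
        }
      }
    }
    list(ints = do.call(rbind, ints), rts = do.call(rbind, rts))
  })
  attr(res$rts, "T_SL") <- fixture$r1rho[[1]]$T_SL
  profiles <- build_profiles(res$rts)
  list(intensities = res$ints, rates = res$rts, profiles = profiles)
}

#' Simulate a fixture end to end
#'
#' Convenience wrapper returning the combined fitting-ready profiles of
#' [simulate_cpmg()] and [simulate_r1rho()] (seeded independently but
#' deterministically from `seed`).
#'
#' @inheritParams simulate_cpmg
#' @return List of [dispersion_profile()]s.
#' @export
simulate_fixture <- function(fixture, seed = fixture$seed) {
  profiles <- list()
  if (length(fixture$cpmg))
    profiles <- c(profiles, simulate_cpmg(fixture, seed = seed)$profiles)
  if (length(fixture$r1rho))
    profiles <- c(profiles,
                  simulate_r1rho(fixture, seed = seed + 1L)$profiles)
  profiles
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Generates a [anisotropy_model()] curve over a protein-concentration
#' grid with additive Gaussian noise expressed as a fraction of the total
#' anisotropy amplitude `s * RNA_conc`.
#'
#' @param K_D dissociation constant (nM).
#' @param RNA_conc labelled-ligand concentration (nM).
#' @param P_grid protein concentrations (nM).
#' @param r_min,s model truth.
#' @param noise noise fraction of the amplitude (e.g. `0.02`).
#' @param replicates replicate curves.
#' @param seed integer seed.
#' @return Data frame with columns `P_conc`, `r_obs`, `replicate`,
#'   `RNA_conc`; truth stored in attributes.
#' @export
simulate_titration <- function(K_D, RNA_conc = 1,
                               P_grid = c(0, 5, 10, 30, 100, 400, 1000),
                               r_min = 0.05, s = 0.15, noise = 0.02,
                               replicates = 1, seed = 1L) {
  stopifnot(K_D > 0, RNA_conc > 0, all(P_grid >= 0))
  amp <- s * RNA_conc
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      m <- anisotropy_model(P_grid, RNA_conc, K_D, r_min, s)
      data.frame(P_conc = P_grid,
                 r_obs = m + rnorm(length(P_grid), 0, noise * amp),
                 replicate = r, RNA_conc = RNA_conc)
    }))
  })
  attr(out, "truth") <- list(K_D = K_D, r_min = r_min, s = s)
  attr(out, "RNA_conc") <- RNA_conc
  out
}

#' Simulate a catalytic turnover time series
#'
#' Linear initial-rate kinetics: product concentration grows as
#' `rate * E0 * t`, substrate decreases accordingly; both signals carry
#' multiplicative Gaussian noise.  Default concentrations follow a
#' standard single-turnover assay (50 uM enzyme, 500 uM slowly hydrolyzed
#' substrate) and the default timepoints stay within 30% conversion.
#'
#' @param rate turnover rate in 1/min.
#' @param E0 enzyme concentration (uM).
#' @param S0 substrate concentration (uM).
#' @param timepoints sampling times in minutes.
#' @param noise relative signal noise (e.g. `0.02`).
#' @param seed integer seed.
#' @return Data frame with columns `time`, `substrate_signal`,
#'   `product_signal`; `E0` / `S0` stored as attributes.
#' @export
simulate_turnover <- function(rate = 0.05, E0 = 50, S0 = 500,
                              timepoints = seq(0, 54, by = 6),
                              noise = 0.02, seed = 1L) {
  stopifnot(rate >= 0, E0 > 0, S0 > 0, all(diff(timepoints) > 0))
  prod <- pmin(rate * E0 * timepoints, S0)
  sub <- S0 - prod
  out <- with_seed(seed, {
    data.frame(
      time = timepoints,
      substrate_signal = sub * (1 + rnorm(length(sub), 0, noise)),
      product_signal = prod * (1 + rnorm(length(prod), 0, noise)))
  })
  attr(out, "E0") <- E0
  attr(out, "S0") <- S0
  attr(out, "truth") <- list(rate = rate)
  out
}
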