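# Plain-text table and JSON input/output.  Dispersion records travel as
# CSV/TSV with an explicit column dictionary rather than any spectrometer
# vendor format: fits start from extracted peak intensities or rates.
# Units are enforced at parse time: temperatures in kelvin, frequencies in
# Hz, delays in seconds, rates in 1/s, shifts in ppm; the static field is
# always the proton Larmor frequency in MHz.

.required_rate_cols <- c("probe_id", "nucleus", "field_MHz",
                         "temperature_K", "experiment", "nu_Hz")

#' Read a dispersion table into fitting-ready profiles
#'
#' Accepts either rate-level tables (column `value` = `R2_eff` or `R1rho`
#' in 1/s, optional `sigma`, optional `replicate`) or intensity-level
#' CPMG tables (columns `intensity`, `I0`, `T_relax_s`, `replicate`),
#' which are converted with [r2eff_from_intensity()].  Records are grouped
#' by probe, field, temperature and experiment type; replicates are
#' aggregated to mean and standard deviation and sigma floors applied
#' (missing sigmas for single measurements become the floor, with a
#' warning).  Unknown columns are ignored; missing required columns are
#' rejected by name.
#'
#' @param path CSV (default) or TSV file path.
#' @param sep field separator.
#' @param floor sigma floor passed to [apply_sigma_floor()] (`NULL` for
#'   the nucleus default).
#' @return List of [dispersion_profile()] objects.
#' @export
read_dispersion_table <- function(path, sep = ",", floor = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_rate_cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  num_cols <- intersect(c("field_MHz", "temperature_K", "nu_Hz", "value",
                          "sigma", "intensity", "I0", "T_relax_s"),
                        names(df))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(v))
      if (length(bad))
        stop("malformed numeric cell in column '", cc, "', row ", bad[1],
             ": '", v[bad[1]], "'")
      df[[cc]] <- conv
    }
  }
  if (!"value" %in% names(df)) {
    needed <- c("intensity", "I0", "T_relax_s")
    if (!all(needed %in% names(df)))
      stop("table has neither 'value' nor intensity columns (",
           paste(needed, collapse = ", "), ")")
    df$value <- mapply(r2eff_from_intensity, df$intensity, df$I0,
                       df$T_relax_s,
                       as.character(seq_len(nrow(df))))
  }
  single <- is.null(df$replicate) ||
    all(tapply(df$replicate,
               interaction(df$probe_id, df$field_MHz, df$temperature_K,
                           df$experiment, df$nu_Hz, drop = TRUE),
               function(x) length(unique(x))) == 1)
  has_sigma <- "sigma" %in% names(df)
  if (single && !has_sigma)
    warning("single replicate and no sigma column; ",
            "uncertainties set to the sigma floor", call. = FALSE)
  groups <- split(df, interaction(df$probe_id, df$field_MHz,
                                  df$temperature_K, df$experiment,
                                  drop = TRUE))
  profiles <- lapply(groups, function(g) {
    if (nrow(g) == 0) {
      warning("empty group skipped", call. = FALSE)
      return(NULL)
    }
    pts <- if (single && has_sigma) {
      data.frame(nu_Hz = g$nu_Hz, value = g$value, sigma = g$sigma,
                 n_rep = 1L)
    } else {
      aggregate_replicates(g)
    }
    p <- dispersion_profile(
      g$probe_id[1], g$nucleus[1], g$field_MHz[1], g$temperature_K[1],
      g$experiment[1], pts,
      T_CPMG = if (g$experiment[1] != "R1rho") g$T_relax_s[1] else NULL,
      T_SL = if ("T_SL_s" %in% names(g))
        sort(unique(g$T_SL_s)) else c(0, 0.004, 0.008, 0.016, 0.032))
    apply_sigma_floor(p, floor = floor)
  })
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]
  names(profiles) <- NULL
  message(length(profiles), " profile(s), ",
          sum(vapply(profiles, function(p) nrow(p$points), 0L)),
          " aggregated points read from ", path)
  profiles
}

#' Write dispersion profiles as a flat rate table
#'
#' Writes the aggregated (post-floor) rate representation; reading the
#' file back with [read_dispersion_table()] reproduces the profiles.
#'
#' @param profiles list of [dispersion_profile()]s.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_dispersion_table <- function(profiles, path, sep = ",") {
  rows <- lapply(profiles, function(p) {
    data.frame(probe_id = p$probe_id, nucleus = p$nucleus,
               field_MHz = p$field_MHz, temperature_K = p$temperature_K,
               experiment = p$experiment, nu_Hz = p$points$nu_Hz,
               T_relax_s = if (is.null(p$T_CPMG)) NA_real_ else p$T_CPMG,
               value = p$points$value, sigma = p$points$sigma,
               n_rep = p$points$n_rep)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result as JSON plus a flat TSV parameter summary
#'
#' @param result an `rd_fit`, optionally carrying Monte Carlo errors via
#'   `mc`.
#' @param path output stem; writes `<path>.json` and `<path>.tsv`.
#' @param mc optional `rd_mc` object from [monte_carlo_errors()] whose
#'   standard deviations are attached as parameter errors.
#' @return The JSON path, invisibly.
#' @export
write_fit_result <- function(result, path, mc = NULL) {
  stopifnot(inherits(result, "rd_fit"))
  se <- setNames(rep(NA_real_, length(result$par)), names(result$par))
  if (!is.null(mc)) se[names(mc$sd)] <- mc$sd
  obj <- list(
    parameters = as.list(result$par),
    errors = as.list(se),
    free = result$free,
    chi2 = result$chi2, chi2nu = result$chi2nu,
    n_points = result$n_points, n_free = result$n_free,
    boundary = result$boundary,
    convergence = result$convergence,
    mc = if (!is.null(mc)) list(n_cycles = mc$n_cycles,
                                n_fail = mc$n_fail, seed = mc$seed))
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  tsv <- data.frame(parameter = names(result$par),
                    value = unname(result$par),
                    error = unname(se),
                    free = names(result$par) %in% result$free)
  write.table(tsv, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(paste0(path, ".json"))
}

#' Run configuration
#'
#' Collects the knobs of an analysis run (inputs, parameter-sharing
#' scopes, sigma floors, seeds, Monte Carlo cycles, output directory)
#' with all defaults explicit, and round-trips through JSON.
#'
#' @param input_paths character vector of dispersion-table paths.
#' @param p_GS_scope,k_ex_scope parameter-sharing scopes (see
#'   [fit_schema()]).
#' @param floor_c13,floor_f19 sigma floors in 1/s.
#' @param seed integer seed for stochastic steps.
#' @param mc_cycles Monte Carlo cycle count.
#' @param out_dir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_paths = character(),
                       p_GS_scope = "global", k_ex_scope = "global",
                       floor_c13 = 0.2, floor_f19 = 2,
                       seed = 1L, mc_cycles = 500L,
                       out_dir = ".") {
  structure(list(input_paths = input_paths,
                 p_GS_scope = p_GS_scope, k_ex_scope = k_ex_scope,
                 floor_c13 = floor_c13, floor_f19 = floor_f19,
                 seed = as.integer(seed), mc_cycles = as.integer(mc_cycles),
                 out_dir = out_dir),
            class = "run_config")
}

#' Serialize / parse a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  problems <- character()
  if (!is.numeric(obj$floor_c13) || obj$floor_c13 < 0)
    problems <- c(problems, "floor_c13 must be a non-negative number")
  if (!is.numeric(obj$floor_f19) || obj$floor_f19 < 0)
    problems <- c(problems, "floor_f19 must be a non-negative number")
  if (!is.numeric(obj$mc_cycles) || obj$mc_cycles < 2)
    problems <- c(problems, "mc_cycles must be >= 2")
  if (!obj$p_GS_scope %in% c("global", "per_temperature", "per_nucleus"))
    problems <- c(problems, "unknown p_GS_scope")
  if (!obj$k_ex_scope %in% c("global", "per_temperature", "per_nucleus"))
    problems <- c(problems, "unknown k_ex_scope")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  do.call(run_config, obj[c("input_paths", "p_GS_scope", "k_ex_scope",
                            "floor_c13", "floor_f19", "seed", "mc_cycles",
                            "out_dir")])
}
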