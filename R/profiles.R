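#' Dispersion profile
#'
#' One measured (or simulated) relaxation dispersion profile: effective
#' relaxation rates versus pulsing frequency for a single probe, field,
#' temperature and experiment type.
#'
#' @param probe_id probe label.
#' @param nucleus detected nucleus (`"13C"`, `"19F"`, ...).
#' @param field_MHz static field as proton Larmor frequency in MHz.
#' @param temperature_K sample temperature in kelvin.
#' @param experiment `"SQ"`, `"MQ"` (CPMG) or `"R1rho"`.
#' @param points data frame with columns `nu_Hz` (CPMG frequency or
#'   spin-lock field), `value` (`R2_eff` or `R1rho`, 1/s), `sigma`
#'   (standard deviation, 1/s; `NA` allowed before flooring) and optionally
#'   `n_rep` (replicate count).
#' @param T_CPMG constant CPMG delay in seconds (CPMG profiles).
#' @param T_SL spin-lock durations in seconds (R1rho profiles).
#' @return An object of class `dispersion_profile`.
#' @export
dispersion_profile <- function(probe_id, nucleus, field_MHz, temperature_K,
                               experiment = c("SQ", "MQ", "R1rho"),
                               points,
                               T_CPMG = NULL,
                               T_SL = c(0, 0.004, 0.008, 0.016, 0.032)) {
  experiment <- match.arg(experiment)
  stopifnot(is.data.frame(points),
            all(c("nu_Hz", "value") %in% names(points)))
  if (is.null(points$sigma)) points$sigma <- NA_real_
  if (is.null(points$n_rep)) points$n_rep <- 1L
  points <- points[order(points$nu_Hz),
                   c("nu_Hz", "value", "sigma", "n_rep")]
  rownames(points) <- NULL
  if (experiment %in% c("SQ", "MQ") && is.null(T_CPMG))
    stop("CPMG profiles need T_CPMG")
  structure(
    list(probe_id = as.character(probe_id), nucleus = nucleus,
         field_MHz = field_MHz, temperature_K = temperature_K,
         experiment = experiment, points = points,
         T_CPMG = T_CPMG, T_SL = T_SL,
         gamma_ratio = gamma_ratio(nucleus)),
    class = "dispersion_profile"
  )
}

#' @export
print.dispersion_profile <- function(x, ...) {
  cat(sprintf("Dispersion profile: %s %s %s, %g MHz, %g K, %d points\n",
              x$probe_id, x$nucleus, x$experiment, x$field_MHz,
              x$temperature_K, nrow(x$points)))
  invisible(x)
}

#' Apply a minimum standard deviation to a dispersion profile
#'
#' Replaces each point uncertainty by `max(sigma, floor)`.  Flooring the
#' replicate-derived standard deviations avoids excessive weighting of
#' points with accidentally low scatter.  The default floor is
#' nucleus-dependent: 0.2 1/s for 13C CPMG data and 2 1/s for 19F data.
#'
#' @param profile a [dispersion_profile()], or a list of them.
#' @param floor minimum standard deviation in 1/s; `NULL` selects the
#'   nucleus default.
#' @return The profile (or list) with floored `sigma`; missing sigmas are
#'   set to the floor.
#' @examples
#' pts <- data.frame(nu_Hz = c(62.5, 125), value = c(150, 140),
#'                   sigma = c(0.5, 5))
#' p <- dispersion_profile("P1", "19F", 500, 313, "SQ", pts, T_CPMG = 0.016)
#' apply_sigma_floor(p)$points$sigma
#' @export
apply_sigma_floor <- function(profile, floor = NULL) {
  if (is.list(profile) && !inherits(profile, "dispersion_profile"))
    return(lapply(profile, apply_sigma_floor, floor = floor))
  stopifnot(inherits(profile, "dispersion_profile"))
  if (is.null(floor))
    floor <- default_sigma_floor(profile$nucleus)
  stopifnot(floor >= 0)
  s <- profile$points$sigma
  s[is.na(s)] <- floor
  profile$points$sigma <- pmax(s, floor)
  attr(profile, "sigma_floor") <- floor
  profile
}

default_sigma_floor <- function(nucleus) {
  switch(nucleus, "13C" = 0.2, "19F" = 2, 0.2)
}

#' Aggregate replicate measurements into one profile point per frequency
#'
#' Replicate rates are averaged to a single value per frequency with
#' `sigma` equal to the sample standard deviation across replicates
#' (`NA` for single measurements, to be handled by the sigma floor).
#'
#' @param df data frame with columns `nu_Hz`, `value` and optionally
#'   `replicate`.
#' @return Data frame with one row per frequency: `nu_Hz`, `value`,
#'   `sigma`, `n_rep`.
#' @export
aggregate_replicates <- function(df) {
  stopifnot(all(c("nu_Hz", "value") %in% names(df)))
  sp <- split(df, df$nu_Hz)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(nu_Hz = d$nu_Hz[1], value = mean(d$value),
               sigma = if (nrow(d) > 1) sd(d$value) else NA_real_,
               n_rep = nrow(d))
  }))
  out <- out[order(out$nu_Hz), ]
  rownames(out) <- NULL
  out
}

# model values for one profile given resolved physical parameters (ppm)
model_profile <- function(profile, p_GS, k_ex, dw_ppm, dwH_ppm = 0,
                          R2_0, R1 = NA_real_, nu = profile$points$nu_Hz) {
  dw <- 2 * pi * dw_ppm * profile$gamma_ratio * profile$field_MHz
  switch(profile$experiment,
    SQ = cpp_sq_cpmg(p_GS, k_ex, dw, R2_0, R2_0, profile$T_CPMG,
                     as.numeric(nu), 0L),
    MQ = {
      dwH <- 2 * pi * dwH_ppm * profile$field_MHz # 1H partner
      cpp_mq_cpmg(p_GS, k_ex, dwH, dw, R2_0, profile$T_CPMG,
                  as.numeric(nu), 0L)
    },
    R1rho = cpp_r1rho(p_GS, k_ex, dw, R2_0, R1, as.numeric(nu), 0L,
                      as.numeric(profile$T_SL), 0, TRUE)
  )
}
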