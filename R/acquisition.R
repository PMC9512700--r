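#' Gyromagnetic ratios relative to the proton
#'
#' Lookup of gamma_X / gamma_H used to convert shift differences from ppm
#' to rad/s at a static field expressed as the proton Larmor frequency.
#'
#' @param nucleus one of `"1H"`, `"13C"`, `"19F"`.
#' @return The ratio gamma_X / gamma_H.
#' @export
gamma_ratio <- function(nucleus) {
  ratios <- c("1H" = 1.0, "13C" = 0.25144, "19F" = 0.94094)
  if (!nucleus %in% names(ratios))
    stop("unknown nucleus '", nucleus, "'; known: ",
         paste(names(ratios), collapse = ", "))
  unname(ratios[[nucleus]])
}

#' Convert a shift difference from ppm to rad/s
#'
#' `dw_rad = 2 * pi * dw_ppm * (gamma_X / gamma_H) * field_MHz`, with the
#' static field given as the proton Larmor frequency in MHz.
#'
#' @param dw_ppm shift difference in ppm.
#' @param nucleus detected nucleus (see [gamma_ratio()]).
#' @param field_MHz proton Larmor frequency of the spectrometer in MHz.
#' @return Shift difference in rad/s.
#' @export
ppm_to_rads <- function(dw_ppm, nucleus, field_MHz) {
  2 * pi * dw_ppm * gamma_ratio(nucleus) * field_MHz
}

#' CPMG acquisition scheme
#'
#' Describes a constant-time CPMG experiment.  The frequency convention is
#' `nu_cpmg = 1 / (2 * tau)` with `tau` the spacing between the centres of
#' successive refocusing pulses, so the pulse count is
#' `N = 2 * T_CPMG * nu_cpmg` and must be a (near-)integer for every
#' frequency on the grid.
#'
#' @param nucleus detected nucleus.
#' @param field_MHz static field as proton Larmor frequency in MHz.
#' @param T_CPMG constant relaxation delay in seconds.
#' @param nu_cpmg vector of CPMG frequencies in Hz, positive and distinct.
#' @param experiment `"SQ"` or `"MQ"`.
#' @param temperature_K sample temperature in kelvin.
#' @return An object of class `cpmg_acquisition`.
#' @examples
#' cpmg_acquisition("19F", 500, T_CPMG = 0.016, nu_cpmg = c(62.5, 125, 250))
#' @export
cpmg_acquisition <- function(nucleus, field_MHz, T_CPMG, nu_cpmg,
                             experiment = c("SQ", "MQ"),
                             temperature_K = 298) {
  experiment <- match.arg(experiment)
  stopifnot(T_CPMG > 0, all(nu_cpmg > 0), !anyDuplicated(nu_cpmg))
  n <- 2 * T_CPMG * nu_cpmg
  bad <- abs(n - round(n)) > 0.05 | round(n) < 1
  if (any(bad))
    stop("CPMG frequencies without an integer pulse count for T_CPMG = ",
         T_CPMG, " s: ", paste(nu_cpmg[bad], collapse = ", "))
  structure(
    list(nucleus = nucleus, field_MHz = field_MHz,
         gamma_ratio = gamma_ratio(nucleus),
         temperature_K = temperature_K, T_CPMG = T_CPMG,
         nu_cpmg = sort(nu_cpmg), experiment = experiment),
    class = "cpmg_acquisition"
  )
}

#' On-resonance spin-lock (R1rho) acquisition scheme
#'
#' @param field_MHz static field as proton Larmor frequency in MHz.
#' @param T_SL spin-lock durations in seconds; must include 0 (the
#'   reference point of the decay).
#' @param nu_SL spin-lock field strengths in Hz, positive.
#' @param nucleus detected nucleus.
#' @param temperature_K sample temperature in kelvin.
#' @param carrier_policy carrier placement rule; `"observed_peak"` places
#'   the carrier at the offset of the dominant component of the averaged
#'   resonance (computed from the exchange matrix eigenvalues), mirroring
#'   acquisition centred on the peak maximum.
#' @return An object of class `r1rho_acquisition`.
#' @export
r1rho_acquisition <- function(field_MHz, T_SL, nu_SL, nucleus = "19F",
                              temperature_K = 298,
                              carrier_policy = "observed_peak") {
  stopifnot(all(nu_SL > 0), all(T_SL >= 0))
  if (!any(T_SL == 0))
    stop("T_SL must include 0")
  structure(
    list(nucleus = nucleus, field_MHz = field_MHz,
         gamma_ratio = gamma_ratio(nucleus),
         temperature_K = temperature_K,
         T_SL = sort(T_SL), nu_SL = sort(nu_SL),
         carrier_policy = carrier_policy),
    class = "r1rho_acquisition"
  )
}
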