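#' Two-state exchange model
#'
#' Constructs the kinetic description of a two-site conformational
#' equilibrium between a ground state (GS) and an excited state (ES):
#' populations `p_GS` and `p_ES = 1 - p_GS`, total exchange rate
#' `k_ex = k_GS_ES + k_ES_GS`, forward rate `k_GS_ES = (1 - p_GS) * k_ex`
#' and backward rate `k_ES_GS = p_GS * k_ex`.  Detailed balance
#' `p_GS * k_GS_ES = p_ES * k_ES_GS` holds by construction.
#'
#' @param p_GS ground-state population, strictly between 0 and 1.
#' @param k_ex exchange rate constant in 1/s, strictly positive.
#' @return An object of class `two_state_exchange` with fields `p_GS`,
#'   `p_ES`, `k_ex`, `k_GS_ES` and `k_ES_GS`.
#' @examples
#' two_state_exchange(p_GS = 0.819, k_ex = 710)
#' @export
two_state_exchange <- function(p_GS, k_ex) {
  stopifnot(is.numeric(p_GS), length(p_GS) == 1L, is.finite(p_GS),
            is.numeric(k_ex), length(k_ex) == 1L, is.finite(k_ex))
  if (p_GS <= 0 || p_GS >= 1)
    stop("p_GS must lie strictly between 0 and 1, got ", p_GS)
  if (k_ex <= 0)
    stop("k_ex must be positive, got ", k_ex)
  structure(
    list(p_GS = p_GS, p_ES = 1 - p_GS, k_ex = k_ex,
         k_GS_ES = (1 - p_GS) * k_ex, k_ES_GS = p_GS * k_ex),
    class = "two_state_exchange"
  )
}

#' @export
print.two_state_exchange <- function(x, ...) {
  cat("Two-state exchange model\n")
  cat(sprintf("  p_GS = %.4f, p_ES = %.4f\n", x$p_GS, x$p_ES))
  cat(sprintf("  k_ex = %.4g 1/s (k_GS_ES = %.4g, k_ES_GS = %.4g)\n",
              x$k_ex, x$k_GS_ES, x$k_ES_GS))
  invisible(x)
}

#' Per-probe spin parameters
#'
#' Chemical-shift differences and intrinsic relaxation rates of one probe
#' (an isotope-labelled methyl group or a fluorine reporter).  Shift
#' differences are stored as magnitudes: relaxation dispersion is blind to
#' the sign of the GS/ES shift difference.
#'
#' @param probe_id probe label.
#' @param delta_omega_X `|dw|` of the detected nucleus in ppm.
#' @param delta_omega_H `|dw_H|` of the proton partner in ppm (MQ
#'   experiments); default 0.
#' @param R2_0 intrinsic transverse relaxation rate(s) in 1/s, optionally
#'   named by `field.experiment` pair.
#' @param R1 longitudinal relaxation rate in 1/s (spin-lock experiments).
#' @return An object of class `probe_params`.
#' @export
probe_params <- function(probe_id, delta_omega_X, delta_omega_H = 0,
                         R2_0 = numeric(), R1 = NA_real_) {
  stopifnot(length(probe_id) == 1L, is.numeric(delta_omega_X),
            is.numeric(delta_omega_H))
  if (any(delta_omega_X < 0) || any(delta_omega_H < 0))
    stop("shift differences are magnitudes and must be >= 0")
  if (any(R2_0 < 0, na.rm = TRUE) || isTRUE(R1 < 0))
    stop("relaxation rates must be >= 0")
  structure(
    list(probe_id = as.character(probe_id),
         delta_omega_X = delta_omega_X, delta_omega_H = delta_omega_H,
         R2_0 = R2_0, R1 = R1),
    class = "probe_params"
  )
}
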