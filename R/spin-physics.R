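#' Effective transverse relaxation rate from peak intensities
#'
#' Converts a normalized peak intensity into an effective transverse
#' relaxation rate assuming mono-exponential decay over the constant
#' relaxation delay: `R2_eff = -log(I_nu / I_0) / T_relax`.
#'
#' @param I_nu signal intensity at the probed pulsing frequency.
#' @param I_0 reference intensity (relaxation element omitted).
#' @param T_relax relaxation delay in seconds.
#' @param record optional record label used in error messages.
#' @return `R2_eff` in 1/s (vectorized over `I_nu`).
#' @seealso [intensity_from_r2eff()] for the exact inverse.
#' @examples
#' r2eff_from_intensity(0.5, 1, 0.024)
#' @export
r2eff_from_intensity <- function(I_nu, I_0, T_relax, record = NULL) {
  stopifnot(is.numeric(I_nu), is.numeric(I_0), T_relax > 0)
  bad <- !is.finite(I_nu) | I_nu <= 0 | !is.finite(I_0) | I_0 <= 0
  if (any(bad)) {
    where <- if (is.null(record)) paste0("element ", which(bad)[1]) else
      paste0("record ", record[bad][1])
    stop("invalid measurement: non-positive intensity at ", where)
  }
  -log(I_nu / I_0) / T_relax
}

#' Peak intensity from an effective relaxation rate
#'
#' Inverse of [r2eff_from_intensity()]: `I_nu = I_0 * exp(-R2_eff * T)`.
#'
#' @param R2_eff effective transverse relaxation rate in 1/s.
#' @param I_0 reference intensity.
#' @param T_relax relaxation delay in seconds.
#' @export
intensity_from_r2eff <- function(R2_eff, I_0, T_relax) {
  stopifnot(T_relax > 0, all(I_0 > 0))
  I_0 * exp(-R2_eff * T_relax)
}

#' Single-quantum CPMG dispersion forward model
#'
#' Effective transverse relaxation rate of a two-state system during a
#' constant-time CPMG element, computed by piecewise matrix-exponential
#' propagation of the 2x2 complex single-quantum evolution matrix
#' (diagonal `-R2 - k_out + i * shift`, off-diagonal the entry rates), with
#' ideal refocusing pulses applied as complex conjugation.
#'
#' With `detection = "eigen"` (default) the rate is the decay rate of the
#' slowest-decaying mode of the two-echo cycle propagator - the quantity
#' the Carver-Richards closed form describes, equivalent to projecting the
#' propagated and the initial magnetization on the dominant component.
#' `detection = "signal"` instead propagates the equilibrium magnetization
#' explicitly and returns `-log(|M(T)| / |M(0)|) / T` for the summed
#' transverse magnetization, which additionally carries the (usually small)
#' amplitude factor of the minor mode.
#'
#' @param model a [two_state_exchange()] object.
#' @param dw GS/ES shift difference of the detected nucleus in rad/s.
#' @param R2_0 intrinsic transverse relaxation rate in 1/s (shared by both
#'   states unless `R2_E` is given).
#' @param acq a [cpmg_acquisition()] object supplying `T_CPMG` (and the
#'   default frequency grid).
#' @param nu CPMG frequency (or vector of frequencies) in Hz; defaults to
#'   `acq$nu_cpmg`.
#' @param R2_E excited-state intrinsic rate; defaults to `R2_0`.
#' @param detection `"eigen"` or `"signal"` (see Details).
#' @return `R2_eff` in 1/s, one value per frequency.
#' @examples
#' mod <- two_state_exchange(0.9, 1000)
#' acq <- cpmg_acquisition("19F", 500, 0.016, c(62.5, 250, 1000))
#' sq_cpmg_r2eff(mod, dw = 400, R2_0 = 20, acq = acq)
#' @export
sq_cpmg_r2eff <- function(model, dw, R2_0, acq, nu = acq$nu_cpmg,
                          R2_E = R2_0, detection = c("eigen", "signal")) {
  detection <- match.arg(detection)
  stopifnot(inherits(model, "two_state_exchange"),
            inherits(acq, "cpmg_acquisition"))
  cpp_sq_cpmg(model$p_GS, model$k_ex, dw, R2_0, R2_E, acq$T_CPMG,
              as.numeric(nu), if (detection == "eigen") 0L else 1L)
}

#' Multiple-quantum CPMG dispersion forward model
#'
#' Effective relaxation rate of methyl-TROSY multiple-quantum coherence
#' during a constant-time CPMG element.  Zero-quantum and double-quantum
#' two-state amplitude vectors evolve with excited-state frequencies
#' `dw_H - dw_C` and `dw_H + dw_C`; each carbon refocusing pulse
#' interconverts ZQ and DQ, and a single proton refocusing pulse at
#' `T_CPMG / 2` swaps coherence order with complex conjugation.  The exact
#' timing of the proton pulse relative to the carbon pulse blocks follows
#' the swap-at-midpoint scheme of the standard MQ dispersion experiment.
#' Detection conventions are as in [sq_cpmg_r2eff()]; the `"eigen"` rate is
#' taken from the two-echo cycle in the ZQ channel (the DQ channel gives
#' the identical magnitude).
#'
#' @inheritParams sq_cpmg_r2eff
#' @param dw_H proton shift difference in rad/s.
#' @param dw_C carbon shift difference in rad/s.
#' @param R2MQ_0 intrinsic multiple-quantum relaxation rate in 1/s.
#' @return `R2_eff` in 1/s, one value per frequency.
#' @export
mq_cpmg_r2eff <- function(model, dw_H, dw_C, R2MQ_0, acq, nu = acq$nu_cpmg,
                          detection = c("eigen", "signal")) {
  detection <- match.arg(detection)
  stopifnot(inherits(model, "two_state_exchange"),
            inherits(acq, "cpmg_acquisition"))
  cpp_mq_cpmg(model$p_GS, model$k_ex, dw_H, dw_C, R2MQ_0, acq$T_CPMG,
              as.numeric(nu), if (detection == "eigen") 0L else 1L)
}

#' Lineshape observables from the free-precession exchange matrix
#'
#' Eigen-decomposes the 2x2 complex free-precession evolution matrix of the
#' exchanging system.  Each eigenvalue yields one spectral component: its
#' offset is the imaginary part, its decay rate the negative real part
#' (full width at half maximum `R2_obs / pi` in Hz), and its amplitude the
#' projection of the equilibrium magnetization (amplitudes sum to 1).  The
#' dominant component defines the observed peak, e.g. for carrier placement
#' in spin-lock experiments.
#'
#' @param model a [two_state_exchange()] object.
#' @param dw shift difference in rad/s (ground state at offset 0).
#' @param R2_G,R2_E intrinsic transverse rates of the two states in 1/s.
#' @return A data frame of class `lineshape_observables` with columns
#'   `offset` (rad/s), `R2_obs` (1/s), `fwhm` (Hz), `amplitude`, and
#'   attribute `dominant` (row index of the observed peak).
#' @examples
#' free_precession_eigen(two_state_exchange(0.5, 913), dw = 440, 115, 115)
#' @export
free_precession_eigen <- function(model, dw, R2_G, R2_E) {
  stopifnot(inherits(model, "two_state_exchange"))
  e <- cpp_free_precession(model$p_GS, model$k_ex, dw, R2_G, R2_E)
  out <- data.frame(offset = e$offset, R2_obs = e$rate,
                    fwhm = e$rate / pi, amplitude = e$amplitude)
  attr(out, "dominant") <- e$dominant
  class(out) <- c("lineshape_observables", "data.frame")
  out
}

#' On-resonance R1rho dispersion forward model
#'
#' Rotating-frame relaxation rate of a two-state system under an
#' on-resonance spin lock, from the 6x6 two-state Bloch-McConnell matrix
#' (x, y, z components per state with intrinsic rates, exchange rates,
#' residual offsets relative to the carrier, and the spin-lock field
#' `2 * pi * nu_SL`).  The carrier is placed at the offset of the observed
#' averaged peak obtained from [free_precession_eigen()], so residual
#' offsets depend on the exchange parameters.
#'
#' `method = "eigen"` (default) returns the decay rate of the rotating-frame
#' mode with dominant overlap with the spin-lock axis.  `method =
#' "propagation"` tilts the equilibrium magnetization into the spin-lock
#' frame, propagates it over each duration in `acq$T_SL` by matrix
#' exponentials and extracts the rate by a mono-exponential fit of the
#' projected magnetization; both paths agree to well within 1%.
#'
#' @param model a [two_state_exchange()] object.
#' @param dw shift difference in rad/s.
#' @param R2_0 intrinsic transverse relaxation rate in 1/s.
#' @param R1 longitudinal relaxation rate in 1/s.
#' @param acq an [r1rho_acquisition()] object.
#' @param nu_SL spin-lock field strength(s) in Hz; defaults to `acq$nu_SL`.
#' @param method `"eigen"` or `"propagation"`.
#' @return `R1rho` in 1/s, one value per spin-lock field.
#' @export
r1rho_onres <- function(model, dw, R2_0, R1, acq, nu_SL = acq$nu_SL,
                        method = c("eigen", "propagation")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "two_state_exchange"),
            inherits(acq, "r1rho_acquisition"))
  cpp_r1rho(model$p_GS, model$k_ex, dw, R2_0, R1, as.numeric(nu_SL),
            if (method == "eigen") 0L else 1L,
            as.numeric(acq$T_SL[acq$T_SL >= 0]),
            0, identical(acq$carrier_policy, "observed_peak"))
}
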