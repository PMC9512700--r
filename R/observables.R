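# Derived quantities of the two-state equilibrium and small consistency
# checks used when interpreting fitted exchange parameters.

#' Forward and backward rates of the two-state equilibrium
#'
#' Decomposes the exchange rate constant into the microscopic rates:
#' `k_GS_ES = (1 - p_GS) * k_ex` (ground to excited) and
#' `k_ES_GS = p_GS * k_ex` (excited to ground); their sum is `k_ex`.
#'
#' @param p_GS ground-state population in `[0, 1]`.
#' @param k_ex exchange rate constant in 1/s.
#' @return An object of class `derived_rates` with `k_GS_ES`, `k_ES_GS`
#'   and the source parameters.
#' @examples
#' forward_backward_rates(0.8, 864)
#' @export
forward_backward_rates <- function(p_GS, k_ex) {
  stopifnot(p_GS >= 0, p_GS <= 1, k_ex >= 0)
  structure(list(k_GS_ES = (1 - p_GS) * k_ex,
                 k_ES_GS = p_GS * k_ex,
                 p_GS = p_GS, k_ex = k_ex),
            class = "derived_rates")
}

#' @export
print.derived_rates <- function(x, ...) {
  cat(sprintf("k_GS_ES = %.4g 1/s, k_ES_GS = %.4g 1/s (k_ex = %.4g)\n",
              x$k_GS_ES, x$k_ES_GS, x$k_ex))
  invisible(x)
}

#' Population-weighted shift difference
#'
#' Expected change of the observed (population-averaged) chemical shift
#' when binding locks the enzyme in the excited conformation:
#' `p_GS * |dw|` in ppm.  Used as a consistency check between dispersion-
#' derived `|dw|` and the shift perturbation measured on ligand addition.
#'
#' @param p_GS ground-state population in `[0, 1]`.
#' @param abs_dw `|dw|` in ppm.
#' @return Expected shift change in ppm.
#' @examples
#' population_weighted_shift(0.8, 0.149)
#' @export
population_weighted_shift <- function(p_GS, abs_dw) {
  stopifnot(all(p_GS >= 0), all(p_GS <= 1), all(abs_dw >= 0))
  p_GS * abs_dw
}

#' Binding free-energy difference from a fold change in affinity
#'
#' `ddG = R * T * log(fold_change)` in kJ/mol, with
#' `R = 8.314 J / (mol K)`.  Quantifies the contribution of a structural
#' element to binding from the ratio of dissociation constants of two
#' constructs.  "Room temperature" defaults to 298 K.
#'
#' @param fold_change ratio `K_D(variant) / K_D(reference)`, `>= 1`.
#' @param T_K absolute temperature in kelvin.
#' @return Free-energy difference in kJ/mol.
#' @examples
#' ddG_from_kd_ratio(3, 298)
#' @export
ddG_from_kd_ratio <- function(fold_change, T_K = 298) {
  stopifnot(T_K > 0)
  if (any(fold_change < 1))
    stop("fold_change must be >= 1 (express the ratio as weaker/stronger)")
  8.314 * T_K * log(fold_change) / 1000
}

#' Chemical shift perturbations between two conditions
#'
#' Per-probe absolute shift difference `|delta_b - delta_a|` for one
#' nucleus.  Probes present in only one record are reported in the
#' `skipped` attribute (with a warning), not silently dropped.  A combined
#' multi-nucleus CSP is deliberately not computed: single-nucleus CSPs
#' compare directly with dispersion-derived `|dw|` of the same nucleus.
#'
#' @param shift_a,shift_b data frames with columns `probe_id` and
#'   `shift_ppm` (one condition each).
#' @return Data frame with columns `probe_id` and `csp_ppm`; attribute
#'   `skipped` lists unmatched probes.
#' @examples
#' a <- data.frame(probe_id = "P1", shift_ppm = 12.50)
#' b <- data.frame(probe_id = "P1", shift_ppm = 12.35)
#' csp(a, b)
#' @export
csp <- function(shift_a, shift_b) {
  stopifnot(all(c("probe_id", "shift_ppm") %in% names(shift_a)),
            all(c("probe_id", "shift_ppm") %in% names(shift_b)))
  common <- intersect(shift_a$probe_id, shift_b$probe_id)
  skipped <- setdiff(union(shift_a$probe_id, shift_b$probe_id), common)
  if (length(skipped))
    warning("probes without a match in both conditions: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  a <- shift_a$shift_ppm[match(common, shift_a$probe_id)]
  b <- shift_b$shift_ppm[match(common, shift_b$probe_id)]
  out <- data.frame(probe_id = common, csp_ppm = abs(b - a))
  attr(out, "skipped") <- skipped
  out
}

#' Linear trend with optional weights
#'
#' Weighted (or unweighted) least-squares line through `(x, y)`, as used
#' for CSP-versus-`|dw|` correlations and for the temperature dependence
#' of rate constants.
#'
#' @param x,y numeric vectors, at least 3 points.
#' @param sigma_y optional standard deviations of `y` (weights
#'   `1 / sigma_y^2`).
#' @return List with `slope`, `intercept`, their standard errors, Pearson
#'   `r` (`NA` with a warning when `y` is constant) and the `lm` fit.
#' @examples
#' linear_trend(1:5, 2 * (1:5) + 1)
#' @export
linear_trend <- function(x, y, sigma_y = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0)
    stop("degenerate predictor: x has zero variance")
  w <- if (is.null(sigma_y)) NULL else 1 / sigma_y^2
  fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
  r <- if (var(y) == 0) {
    warning("y is constant; correlation undefined", call. = FALSE)
    NA_real_
  } else cor(x, y)
  cf <- suppressWarnings(summary(fit))$coefficients # exact fits are fine
  list(slope = cf["x", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       slope_se = cf["x", "Std. Error"],
       intercept_se = cf["(Intercept)", "Std. Error"],
       r = r, fit = fit)
}
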