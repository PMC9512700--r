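# Single-site binding from fluorescence anisotropy and catalytic turnover
# from substrate/product time series.

#' Single-site anisotropy binding model
#'
#' Observed anisotropy of a labelled ligand titrated with protein, with
#' ligand depletion treated exactly via the quadratic solution for the
#' complex concentration:
#' `r_obs = r_min + s * (([RNA] + [P] + K_D) / 2 -
#'   sqrt((([RNA] + [P] + K_D) / 2)^2 - [RNA] * [P]))`.
#' The discriminant is non-negative for all physical concentrations, so
#' the complex term is always real.  At `[P] = 0` the model returns
#' `r_min`; for `[P] -> Inf` it saturates at `r_min + s * [RNA]`.
#'
#' @param P protein concentration(s), same unit as `RNA` (typically nM).
#' @param RNA labelled-ligand concentration.
#' @param K_D dissociation constant.
#' @param r_min anisotropy of the free ligand.
#' @param s scaling factor (anisotropy change per unit complex).
#' @return Observed anisotropy, vectorized over `P`.
#' @export
anisotropy_model <- function(P, RNA, K_D, r_min, s) {
  h <- (RNA + P + K_D) / 2
  r_min + s * (h - sqrt(pmax(h^2 - RNA * P, 0)))
}

#' Fit a single-site binding model to an anisotropy titration
#'
#' Least-squares fit of `(K_D, r_min, s)` of [anisotropy_model()] to a
#' titration curve.  The fit is unweighted by default; when the curve
#' carries replicates, `K_D` is additionally refitted per replicate and
#' the standard deviation across replicates is reported as the error
#' (taking precedence over the covariance-based standard error).
#'
#' @param curve a data frame (or [simulate_titration()] output) with
#'   columns `P_conc`, `r_obs` and optionally `replicate`; the
#'   labelled-ligand concentration is taken from column `RNA_conc` or the
#'   `RNA_conc` attribute.
#' @param weights optional per-point weights.
#' @return Object of class `binding_fit`: list with `K_D`, `r_min`, `s`,
#'   `K_D_se` (replicate s.d. when available, else covariance standard
#'   error), `per_replicate` (data frame or `NULL`) and `fit`.
#' @examples
#' cur <- simulate_titration(K_D = 10, RNA_conc = 1, noise = 0, seed = 1)
#' anisotropy_fit(cur)$K_D
#' @export
anisotropy_fit <- function(curve, weights = NULL) {
  RNA <- curve$RNA_conc[1]
  if (is.null(RNA)) RNA <- attr(curve, "RNA_conc")
  stopifnot(!is.null(RNA), RNA > 0,
            all(c("P_conc", "r_obs") %in% names(curve)))
  if (length(unique(curve$P_conc)) < 5)
    stop("need at least 5 distinct titration points")
  one_fit <- function(d, w) {
    r0 <- min(d$r_obs)
    amp <- max(d$r_obs) - r0
    s0 <- max(amp / RNA, 1e-8)
    K0 <- max(median(d$P_conc[d$P_conc > 0]), 1e-3)
    resid <- function(th) {
      m <- anisotropy_model(d$P_conc, RNA, th[1], th[2], th[3])
      rs <- d$r_obs - m
      if (!is.null(w)) rs * sqrt(w) else rs
    }
    minpack.lm::nls.lm(par = c(K_D = K0, r_min = r0, s = s0), fn = resid,
                       lower = c(1e-6, -Inf, 0),
                       upper = c(1e6, Inf, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- one_fit(curve, weights)
  if (!fit$info %in% 1:4)
    stop("anisotropy fit did not converge: ", fit$message)
  th <- fit$par
  if (th[["K_D"]] <= 2e-6 || th[["K_D"]] >= 0.99e6)
    stop("K_D at a bound; titration does not constrain the affinity")
  cv <- tryCatch(sqrt(diag(solve(fit$hessian)) * 2 *
                        fit$deviance / max(1, length(curve$r_obs) - 3)),
                 error = function(e) rep(NA_real_, 3))
  per_rep <- NULL
  kd_se <- cv[1]
  if (!is.null(curve$replicate) && length(unique(curve$replicate)) > 1) {
    reps <- lapply(split(curve, curve$replicate), function(d) {
      f <- tryCatch(one_fit(d, NULL), error = function(e) NULL)
      if (!is.null(f) && f$info %in% 1:4) f$par[["K_D"]] else NA_real_
    })
    per_rep <- data.frame(replicate = names(reps),
                          K_D = unlist(reps), row.names = NULL)
    if (sum(!is.na(per_rep$K_D)) > 1)
      kd_se <- sd(per_rep$K_D, na.rm = TRUE)
  }
  structure(list(K_D = th[["K_D"]], r_min = th[["r_min"]], s = th[["s"]],
                 K_D_se = kd_se, per_replicate = per_rep, fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Single-site binding fit: K_D = %.3g +/- %.2g, r_min = %.4g, s = %.4g\n",
              x$K_D, x$K_D_se, x$r_min, x$s))
  invisible(x)
}

#' Catalytic turnover rate from a substrate/product time series
#'
#' Converts integrated substrate and product signals to the product
#' fraction `f = product / (product + substrate)` (robust to arbitrary
#' intensity units), fits `f` versus time linearly inside the initial-rate
#' window (first 30% conversion) and scales the slope to a per-enzyme
#' rate: `rate = slope * S0 / E0` in 1/min.
#'
#' @param series data frame with columns `time` (minutes, strictly
#'   increasing), `substrate_signal`, `product_signal`, or a
#'   [simulate_turnover()] output carrying `E0` / `S0` attributes.
#' @param E0 enzyme concentration (same unit as `S0`); defaults to the
#'   `E0` attribute.
#' @param S0 initial substrate concentration; defaults to the `S0`
#'   attribute.
#' @param max_conversion upper edge of the fitted window (default 0.3).
#' @return List with `rate` (1/min), `rate_se`, `slope`, `n_used`, and
#'   `window_warning` (`TRUE` when the whole series exceeds the window).
#' @examples
#' ts <- simulate_turnover(rate = 0.05, noise = 0, seed = 1)
#' turnover_rate(ts)$rate
#' @export
turnover_rate <- function(series, E0 = attr(series, "E0"),
                          S0 = attr(series, "S0"), max_conversion = 0.3) {
  stopifnot(all(c("time", "substrate_signal", "product_signal") %in%
                  names(series)),
            !is.null(E0), !is.null(S0), E0 > 0, S0 > 0)
  if (any(diff(series$time) <= 0))
    stop("time must be strictly increasing")
  tot <- series$substrate_signal + series$product_signal
  if (any(tot <= 0)) stop("non-positive total signal")
  f <- series$product_signal / tot
  keep <- f <= max_conversion
  window_warning <- FALSE
  if (sum(keep) < 3) {
    window_warning <- TRUE
    warning("fewer than 3 points within ", max_conversion * 100,
            "% conversion; using the earliest 3 points", call. = FALSE)
    keep <- seq_along(f) <= 3
  }
  fit <- lm(f[keep] ~ series$time[keep])
  slope <- unname(coef(fit)[2])
  se <- suppressWarnings(summary(fit))$coefficients[2, "Std. Error"]
  if (slope < -1e-12)
    warning("negative product-formation slope", call. = FALSE)
  list(rate = slope * S0 / E0, rate_se = se * S0 / E0,
       slope = slope, n_used = sum(keep),
       window_warning = window_warning)
}

#' Ratio of turnover rates of two series
#'
#' Relative degradation rate `rate_a / rate_b` with the relative errors
#' of the two linear fits propagated in quadrature.
#'
#' @param series_a,series_b inputs accepted by [turnover_rate()].
#' @param ... passed to [turnover_rate()].
#' @return List with `ratio` and `ratio_se`.
#' @export
relative_rate <- function(series_a, series_b, ...) {
  a <- turnover_rate(series_a, ...)
  b <- turnover_rate(series_b, ...)
  if (b$rate <= 0)
    stop("denominator turnover rate is not positive")
  ratio <- a$rate / b$rate
  rel <- sqrt((a$rate_se / a$rate)^2 + (b$rate_se / b$rate)^2)
  list(ratio = ratio, ratio_se = abs(ratio) * rel)
}
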