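# Global weighted least-squares fitting of dispersion profiles with shared
# two-state exchange parameters.

# resolved parameter values (free + fixed) for one profile
profile_pars <- function(keys, full) {
  list(p_GS = full[[keys$p_GS]], k_ex = full[[keys$k_ex]],
       dw = full[[keys$dw]],
       dwH = if (!is.null(keys$dwH)) full[[keys$dwH]] else 0,
       R2_0 = full[[keys$R2_0]],
       R1 = if (!is.null(keys$R1)) full[[keys$R1]] else NA_real_)
}

model_values <- function(theta, profiles, schema) {
  full <- c(theta, schema$fixed)
  lapply(seq_along(profiles), function(i) {
    pp <- profile_pars(schema$map[[i]], full)
    model_profile(profiles[[i]], pp$p_GS, pp$k_ex, pp$dw, pp$dwH,
                  pp$R2_0, pp$R1)
  })
}

check_fit_inputs <- function(profiles, schema) {
  for (p in profiles) {
    s <- p$points$sigma
    if (anyNA(s) || any(s <= 0))
      stop("profile ", p$probe_id, " (", p$experiment,
           ") has missing or non-positive sigma; apply_sigma_floor() first")
    if (nrow(p$points) < 4)
      stop("profile ", p$probe_id, " (", p$experiment,
           ") has fewer than 4 points")
  }
  invisible(TRUE)
}

#' Global fit of dispersion profiles to a two-state exchange model
#'
#' Minimizes the weighted sum of squares
#' `sum(((value - model) / sigma)^2)` over all points of all profiles,
#' with parameter sharing declared by the schema.  The forward model of
#' each profile is selected by its experiment type ([sq_cpmg_r2eff()],
#' [mq_cpmg_r2eff()] or [r1rho_onres()]).  Optimization uses
#' Levenberg-Marquardt trust-region least squares
#' ([minpack.lm::nls.lm()]) with finite-difference gradients, restarted
#' from every point of the schema's multi-start grid over `(p_GS, k_ex)`
#' (two-state dispersion fits are multimodal); the best converged start is
#' returned.
#'
#' @param profiles list of [dispersion_profile()] objects with positive
#'   uncertainties (see [apply_sigma_floor()]).
#' @param schema a [fit_schema()]; defaults to
#'   `fit_schema(profiles)` (global exchange parameters).
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `rd_fit` with elements `par` (all resolved
#'   parameter values, free and fixed), `free` (free parameter names),
#'   `chi2`, `chi2nu` (`chi2 / (n_points - n_free)`), `n_points`,
#'   `n_free`, `starts` (per-start diagnostics), `boundary` (free
#'   parameters that ended on a box constraint), `schema` and
#'   `convergence`.
#' @examples
#' \donttest{
#' fx <- fixture_f19_single()
#' sim <- simulate_r1rho(fx)
#' fit <- fit_global(sim$profiles)
#' fit$par[c("pGS", "kex")]
#' }
#' @export
fit_global <- function(profiles, schema = fit_schema(profiles),
                       maxiter = 300) {
  stopifnot(inherits(schema, "fit_schema"))
  check_fit_inputs(profiles, schema)
  values <- unlist(lapply(profiles, function(p) p$points$value))
  sigmas <- unlist(lapply(profiles, function(p) p$points$sigma))
  residual <- function(theta) {
    names(theta) <- schema$params$name
    (values - unlist(model_values(theta, profiles, schema))) / sigmas
  }
  runs <- lapply(seq_len(nrow(schema$starts)), function(k) {
    th0 <- schema_init(schema, profiles,
                       schema$starts$p_GS[k], schema$starts$k_ex[k])
    out <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = residual,
                         lower = schema$params$lower,
                         upper = schema$params$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) e)
    out
  })
  diag_tab <- data.frame(
    p_GS_start = schema$starts$p_GS, k_ex_start = schema$starts$k_ex,
    chi2 = vapply(runs, function(r)
      if (inherits(r, "nls.lm")) r$deviance else NA_real_, 0),
    info = vapply(runs, function(r)
      if (inherits(r, "nls.lm")) r$info else NA_integer_, 0L),
    message = vapply(runs, function(r)
      if (inherits(r, "nls.lm")) r$message else conditionMessage(r), "")
  )
  ok <- which(diag_tab$info %in% 1:4)
  if (!length(ok)) {
    msg <- paste(utils::capture.output(print(diag_tab)), collapse = "\n")
    stop("no start converged; per-start diagnostics:\n", msg)
  }
  best <- runs[[ok[which.min(diag_tab$chi2[ok])]]]
  theta <- best$par
  names(theta) <- schema$params$name
  tol <- 1e-6
  on_bound <- schema$params$name[
    theta <= schema$params$lower + tol * pmax(1, abs(schema$params$lower)) |
    theta >= schema$params$upper - tol * pmax(1, abs(schema$params$upper))]
  n_points <- length(values)
  n_free <- length(theta)
  fit <- structure(
    list(par = c(theta, schema$fixed), free = names(theta),
         chi2 = best$deviance,
         chi2nu = best$deviance / (n_points - n_free),
         n_points = n_points, n_free = n_free,
         starts = diag_tab, boundary = on_bound,
         convergence = list(info = best$info, message = best$message,
                            niter = best$niter),
         schema = schema, seed = NA_integer_),
    class = "rd_fit")
  if (length(on_bound))
    warning("parameters at a box constraint: ",
            paste(on_bound, collapse = ", "),
            "; the corresponding quantities may be unidentifiable",
            call. = FALSE)
  fit
}

#' @export
print.rd_fit <- function(x, ...) {
  cat(sprintf("Two-state dispersion fit: %d points, %d free parameters\n",
              x$n_points, x$n_free))
  cat(sprintf("  chi2 = %.4g, reduced chi2 = %.4g\n", x$chi2, x$chi2nu))
  ex <- grep("^(pGS|kex)", x$free, value = TRUE)
  for (nm in ex) cat(sprintf("  %s = %.4g\n", nm, x$par[[nm]]))
  if (length(x$boundary))
    cat("  at bounds:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Multi-temperature global fit with one shared shift difference
#'
#' Fits dispersion profiles acquired at several temperatures
#' simultaneously with a single global `|dw|` per probe and independent
#' `(p_GS, k_ex)` per temperature.  Intrinsic rates remain per profile
#' and per temperature.  With a single temperature this reduces exactly to
#' [fit_global()].
#'
#' @inheritParams fit_global
#' @param ... passed to [fit_schema()] (e.g. `fixed`, `starts`, `bounds`).
#' @return An `rd_fit` object (see [fit_global()]).
#' @export
fit_temperature_series <- function(profiles, ..., maxiter = 300) {
  schema <- fit_schema(profiles, p_GS_scope = "per_temperature",
                       k_ex_scope = "per_temperature", ...)
  fit_global(profiles, schema, maxiter = maxiter)
}

#' Joint fit of datasets from two nuclei with a shared exchange rate
#'
#' Combines (for example) 13C methyl CPMG profiles and 19F CPMG / R1rho
#' profiles acquired at one temperature into a single fit sharing `k_ex`
#' (and optionally `p_GS`) across nuclei, while shift differences and
#' intrinsic rates remain nucleus- and probe-specific.  If either profile
#' list is empty the call reduces to [fit_global()] on the other.
#'
#' @param profiles_a,profiles_b lists of [dispersion_profile()] objects,
#'   one per nucleus.
#' @param share_p_GS share `p_GS` across nuclei (default) or fit one per
#'   nucleus.
#' @inheritParams fit_temperature_series
#' @return An `rd_fit` object (see [fit_global()]).
#' @export
fit_joint_nuclei <- function(profiles_a, profiles_b, share_p_GS = TRUE,
                             ..., maxiter = 300) {
  if (!length(profiles_a)) return(fit_global(profiles_b, maxiter = maxiter))
  if (!length(profiles_b)) return(fit_global(profiles_a, maxiter = maxiter))
  profiles <- c(profiles_a, profiles_b)
  temps <- unique(vapply(profiles, function(p) p$temperature_K, 0))
  if (length(temps) > 1)
    stop("joint nuclei fits expect a single temperature, got: ",
         paste(temps, collapse = ", "))
  schema <- fit_schema(profiles,
                       p_GS_scope = if (share_p_GS) "global"
                                    else "per_nucleus",
                       k_ex_scope = "global", ...)
  fit_global(profiles, schema, maxiter = maxiter)
}
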