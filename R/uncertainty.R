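# Monte Carlo parameter uncertainties and reduced chi-square surfaces.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

perturb_profiles <- function(profiles) {
  lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    n <- nrow(p$points)
    p$points$value <- p$points$value + rnorm(n, 0, p$points$sigma)
    p
  })
}

refit_from <- function(theta0, profiles, schema, maxiter = 100) {
  values <- unlist(lapply(profiles, function(p) p$points$value))
  sigmas <- unlist(lapply(profiles, function(p) p$points$sigma))
  residual <- function(theta) {
    names(theta) <- schema$params$name
    (values - unlist(model_values(theta, profiles, schema))) / sigmas
  }
  minpack.lm::nls.lm(par = theta0, fn = residual,
                     lower = schema$params$lower,
                     upper = schema$params$upper,
                     control = minpack.lm::nls.lm.control(maxiter = maxiter))
}

#' Monte Carlo parameter uncertainties for a dispersion fit
#'
#' Repeats the fit on synthetic datasets in which every measured rate is
#' perturbed by a centred Gaussian with its own standard deviation, and
#' returns the standard deviation of each free parameter over the cycles.
#' Each cycle restarts the optimizer from the best-fit solution.  The
#' result is deterministic given `seed`.
#'
#' @param result an `rd_fit` from [fit_global()] and friends.
#' @param profiles the profiles that were fitted.
#' @param n_cycles number of Monte Carlo cycles (default 500).
#' @param seed integer seed for the perturbations.
#' @return An object of class `rd_mc`: list with `sd` (named standard
#'   deviations), `draws` (cycles x parameters matrix of refitted values),
#'   `n_fail`, `n_cycles` and `seed`.
#' @export
monte_carlo_errors <- function(result, profiles, n_cycles = 500, seed = 1) {
  stopifnot(inherits(result, "rd_fit"), n_cycles >= 2)
  schema <- result$schema
  check_fit_inputs(profiles, schema)
  theta_best <- result$par[result$free]
  draws <- matrix(NA_real_, n_cycles, length(theta_best),
                  dimnames = list(NULL, result$free))
  fails <- integer(0)
  with_seed(seed, {
    for (cyc in seq_len(n_cycles)) {
      pert <- perturb_profiles(profiles)
      out <- tryCatch(refit_from(theta_best, pert, schema),
                      error = function(e) e)
      if (inherits(out, "nls.lm") && out$info %in% 1:4) {
        draws[cyc, ] <- out$par
      } else {
        fails <- c(fails, cyc)
      }
    }
  })
  if (length(fails) > 0.1 * n_cycles)
    stop(length(fails), " of ", n_cycles,
         " Monte Carlo cycles failed to converge (cycles ",
         paste(utils::head(fails, 10), collapse = ", "), " ...)")
  structure(list(sd = apply(draws, 2, sd, na.rm = TRUE),
                 draws = draws, n_fail = length(fails),
                 n_cycles = n_cycles, seed = seed),
            class = "rd_mc")
}

#' @export
print.rd_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo errors (%d cycles, %d failed, seed %d)\n",
              x$n_cycles, x$n_fail, x$seed))
  print(signif(x$sd, 3))
  invisible(x)
}

#' Reduced chi-square surface of one fit parameter
#'
#' Systematically fixes the probed parameter at each grid value and
#' re-optimizes all other free parameters, recording the constrained
#' reduced chi-square.  The curvature of the surface reflects the
#' identifiability of the parameter; its minimum agrees with the
#' unconstrained reduced chi-square within numerical tolerance when the
#' grid spans the best-fit value.
#'
#' @param result an `rd_fit`.
#' @param profiles the fitted profiles.
#' @param param_name name of a free parameter of the fit.
#' @param grid numeric vector of values at which to fix the parameter.
#' @return An object of class `rd_chi2_surface`: data frame with columns
#'   `value`, `chi2`, `chi2nu`, `converged`; failed grid points are
#'   flagged, not dropped.
#' @export
chi2_surface <- function(result, profiles, param_name, grid) {
  stopifnot(inherits(result, "rd_fit"),
            param_name %in% result$free, length(grid) >= 2)
  schema <- result$schema
  keep <- schema$params$name != param_name
  sub <- schema
  sub$params <- schema$params[keep, , drop = FALSE]
  theta0 <- result$par[sub$params$name]
  dof <- result$n_points - result$n_free # probed parameter still counted
  rows <- lapply(grid, function(v) {
    sub$fixed <- c(schema$fixed, setNames(v, param_name))
    out <- tryCatch(refit_from(theta0, profiles, sub),
                    error = function(e) e)
    if (inherits(out, "nls.lm") && out$info %in% 1:4)
      data.frame(value = v, chi2 = out$deviance,
                 chi2nu = out$deviance / dof, converged = TRUE)
    else
      data.frame(value = v, chi2 = NA_real_, chi2nu = NA_real_,
                 converged = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "param") <- param_name
  attr(out, "chi2nu_unconstrained") <- result$chi2 / dof
  class(out) <- c("rd_chi2_surface", "data.frame")
  out
}
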