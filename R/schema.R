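#' Parameter-sharing schema for global dispersion fits
#'
#' Declares how model parameters are shared across a set of dispersion
#' profiles.  Exchange parameters (`p_GS`, `k_ex`) can be global, per
#' temperature or per nucleus; shift differences are per probe (one
#' `|dw|`, and for MQ profiles one `|dw_H|`, shared across fields,
#' experiment types and temperatures); intrinsic rates `R2_0` are per
#' probe x field x experiment type x temperature, and `R1` per probe x
#' field x temperature for spin-lock profiles.
#'
#' @param profiles list of [dispersion_profile()] objects.
#' @param p_GS_scope,k_ex_scope one of `"global"`, `"per_temperature"`,
#'   `"per_nucleus"`.
#' @param fixed named numeric vector of parameters to hold fixed.
#' @param bounds named list overriding default box constraints; entries
#'   among `p_GS`, `k_ex`, `dw`, `dwH`, `R2_0`, `R1`, each `c(lower,
#'   upper)`.  Defaults: `p_GS` in (0.5, 0.995) so the minor state is the
#'   excited state, `k_ex` in (10, 1e5) 1/s, `|dw|` in (0, 10) ppm,
#'   `|dw_H|` in (0, 2) ppm, `R2_0` in (0.1, 500) 1/s, `R1` in
#'   (0.01, 50) 1/s.
#' @param starts data frame with columns `p_GS`, `k_ex` giving the
#'   multi-start grid; defaults to `k_ex` in `c(1e2, 1e3, 1e4)` crossed
#'   with `p_GS` in `c(0.6, 0.9)`.
#' @param fit_R1 fit the longitudinal rate of spin-lock profiles
#'   (default `FALSE`).  An on-resonance spin lock tilts the
#'   magnetization to about 90 degrees, so the decay carries essentially
#'   no R1 information; by default R1 is held at `R1_value`, the value an
#'   independent longitudinal-relaxation measurement would supply.
#' @param R1_value fixed R1 in 1/s when `fit_R1 = FALSE`.
#' @return An object of class `fit_schema` with elements `params` (a data
#'   frame of free-parameter names and bounds), `map` (per-profile
#'   parameter resolution), `fixed` and `starts`.
#' @export
fit_schema <- function(profiles,
                       p_GS_scope = c("global", "per_temperature",
                                      "per_nucleus"),
                       k_ex_scope = p_GS_scope[1],
                       fixed = NULL,
                       bounds = list(),
                       starts = NULL,
                       fit_R1 = FALSE,
                       R1_value = 2) {
  p_GS_scope <- match.arg(p_GS_scope)
  k_ex_scope <- match.arg(k_ex_scope,
                          c("global", "per_temperature", "per_nucleus"))
  stopifnot(length(profiles) > 0,
            all(vapply(profiles, inherits, TRUE, "dispersion_profile")))

  b <- modifyList(list(p_GS = c(0.5, 0.995), k_ex = c(10, 1e5),
                       dw = c(0, 10), dwH = c(0, 2),
                       R2_0 = c(0.1, 500), R1 = c(0.01, 50)),
                  bounds)

  tkey <- function(p) paste0(format(p$temperature_K, trim = TRUE), "K")
  scope_key <- function(base, scope, p) {
    switch(scope,
           global = base,
           per_temperature = paste0(base, ".", tkey(p)),
           per_nucleus = paste0(base, ".", p$nucleus))
  }
  # a single level collapses scoped parameters to global naming
  if (length(unique(vapply(profiles,
                           function(p) tkey(p), ""))) == 1L) {
    if (p_GS_scope == "per_temperature") p_GS_scope <- "global"
    if (k_ex_scope == "per_temperature") k_ex_scope <- "global"
  }
  if (length(unique(vapply(profiles,
                           function(p) p$nucleus, ""))) == 1L) {
    if (p_GS_scope == "per_nucleus") p_GS_scope <- "global"
    if (k_ex_scope == "per_nucleus") k_ex_scope <- "global"
  }

  map <- lapply(profiles, function(p) {
    keys <- list(
      p_GS = scope_key("pGS", p_GS_scope, p),
      k_ex = scope_key("kex", k_ex_scope, p),
      dw = paste("dw", p$probe_id, sep = "."),
      R2_0 = paste("R20", p$probe_id, p$field_MHz, p$experiment,
                   tkey(p), sep = ".")
    )
    if (p$experiment == "MQ")
      keys$dwH <- paste("dwH", p$probe_id, sep = ".")
    if (p$experiment == "R1rho")
      keys$R1 <- paste("R1", p$probe_id, p$field_MHz, tkey(p), sep = ".")
    keys
  })

  all_keys <- unique(unlist(map, use.names = FALSE))
  role_of <- function(k) sub("\\..*$", "", k)
  role2bound <- c(pGS = "p_GS", kex = "k_ex", dw = "dw", dwH = "dwH",
                  R20 = "R2_0", R1 = "R1")
  params <- data.frame(
    name = all_keys,
    role = unname(role2bound[role_of(all_keys)]),
    stringsAsFactors = FALSE
  )
  params$lower <- vapply(params$role, function(r) b[[r]][1], 0)
  params$upper <- vapply(params$role, function(r) b[[r]][2], 0)

  fixed <- if (is.null(fixed)) numeric(0) else unlist(fixed)
  if (!fit_R1) {
    r1_keys <- setdiff(grep("^R1\\.", all_keys, value = TRUE),
                       names(fixed))
    fixed <- c(fixed, setNames(rep(R1_value, length(r1_keys)), r1_keys))
  }
  unknown <- setdiff(names(fixed), params$name)
  if (length(unknown))
    stop("fixed parameters not present in the schema: ",
         paste(unknown, collapse = ", "))
  params <- params[!params$name %in% names(fixed), , drop = FALSE]
  rownames(params) <- NULL

  if (is.null(starts))
    starts <- expand.grid(k_ex = c(1e2, 1e3, 1e4), p_GS = c(0.6, 0.9))

  structure(list(params = params, map = map, fixed = fixed,
                 bounds = b, starts = starts,
                 p_GS_scope = p_GS_scope, k_ex_scope = k_ex_scope),
            class = "fit_schema")
}

#' @export
print.fit_schema <- function(x, ...) {
  cat(sprintf("Fit schema: %d free parameters (%s), %d fixed\n",
              nrow(x$params),
              paste(unique(x$params$role), collapse = ", "),
              length(x$fixed)))
  invisible(x)
}

# initial free-parameter vector for one multi-start point
schema_init <- function(schema, profiles, p_GS0, k_ex0) {
  par <- numeric(nrow(schema$params))
  names(par) <- schema$params$name
  full <- function(k, default) if (k %in% names(par)) par[[k]] else
    if (k %in% names(schema$fixed)) schema$fixed[[k]] else default
  for (i in seq_len(nrow(schema$params))) {
    nm <- schema$params$name[i]
    role <- schema$params$role[i]
    par[i] <- switch(role,
      p_GS = p_GS0,
      k_ex = k_ex0,
      dwH = 0.05,
      R1 = 2,
      dw = {
        # crude fast-exchange estimate from the dispersion amplitude
        idx <- which(vapply(schema$map, function(m) m$dw == nm, TRUE))
        amp <- max(vapply(idx, function(j) {
          v <- profiles[[j]]$points$value
          max(v) - min(v)
        }, 0), 1)
        p <- profiles[[idx[1]]]
        sqrt(amp * k_ex0 / (p_GS0 * (1 - p_GS0))) /
          (2 * pi * p$gamma_ratio * p$field_MHz)
      },
      R2_0 = {
        idx <- which(vapply(schema$map,
                            function(m) m$R2_0 == nm, TRUE))
        min(vapply(idx, function(j) min(profiles[[j]]$points$value), 0))
      }
    )
  }
  pmin(pmax(par, schema$params$lower + 1e-8),
       schema$params$upper - 1e-8)
}
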