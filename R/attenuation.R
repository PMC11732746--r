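#' Pool flux records into attenuation profiles
#'
#' Groups total-flux records into the profiles a power-law attenuation fit
#' is run on. Two pooling rules are supported, mirroring how the two cruises
#' were analysed: `"by_occupation"` fits one profile per station occupation
#' (used for the Atlantic cruise, where each occupation of the bloom station
#' and the control station is fitted separately) and `"by_station"` pools
#' all occupations of a station into a single profile (used for the Pacific
#' cruise, where few deployments per occupation and no clear temporal trend
#' justify pooling). Substances never mix: profiles always partition by
#' substance. Every input record is assigned to exactly one profile.
#'
#' @param fluxes Output of [compute_fluxes()]; needs `cruise`, `station`,
#'   `substance`, `depth_m`, `f_total` and (for `"by_occupation"`)
#'   `occupation`.
#' @param rule `"by_station"` or `"by_occupation"`.
#' @return The input with a `profile` identifier column appended; the
#'   attribute `"unfit"` lists profiles with fewer than 3 positive-flux
#'   points (emitted but not fittable).
#' @export
pool_profiles <- function(fluxes, rule = c("by_station", "by_occupation")) {
  rule <- match.arg(rule)
  keys <- switch(rule,
    by_station = c("cruise", "station", "substance"),
    by_occupation = c("cruise", "station", "occupation", "substance")
  )
  miss <- setdiff(c(keys, "depth_m", "f_total"), names(fluxes))
  if (length(miss) > 0) {
    stop("pool_profiles: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- fluxes
  d$profile <- do.call(paste, c(lapply(keys, function(k) as.character(d[[k]])),
                                sep = "|"))
  usable <- tapply(d$f_total > 0 & is.finite(d$f_total), d$profile, sum)
  attr(d, "unfit") <- names(usable)[usable < 3]
  d
}

#' Fit Martin's power-law flux attenuation coefficient
#'
#' Fits `F(z) = F0 * (z / z0)^-b` to a flux-depth profile by ordinary least
#' squares of `ln F` on `ln(z / z0)` — the log-log linearisation whose slope
#' standard error gives the uncertainty on `b`. A larger `b` means faster
#' loss of flux with depth. The reference depth `z0` defaults to the
#' shallowest deployment depth in the profile. Non-positive fluxes, for
#' which the logarithm is undefined, are excluded from the fit and counted
#' in `n_excluded_nonpositive`.
#'
#' @param depth_m Deployment depths, m; strictly positive.
#' @param f_total Total fluxes at those depths.
#' @param sd_f_total Optional flux standard deviations; only used when
#'   `weighted = TRUE` (inverse-variance weights on `ln F`, delta-method
#'   `sd/F`). The default fit is unweighted.
#' @param z0 Reference depth, m; default shallowest depth among the points.
#' @param scheme Label stored on the fit (`"fixed_vfast"`, `"minimized"`,
#'   `"maximized"`).
#' @param weighted Use inverse-variance weighting; default `FALSE`.
#' @return An object of class `martin_fit`: list with `b`, `b_se`, `ln_f0`,
#'   `ln_f0_se`, `z0`, `n_points`, `n_excluded_nonpositive`, `r_squared`,
#'   `df_residual`, `scheme`.
#' @examples
#' fit_martin_b(c(60, 110, 250, 500), c(100, 60, 30, 15))
#' @export
fit_martin_b <- function(depth_m, f_total, sd_f_total = NULL, z0 = NULL,
                         scheme = "fixed_vfast", weighted = FALSE) {
  if (length(depth_m) != length(f_total)) {
    stop("fit_martin_b: depth_m and f_total lengths differ", call. = FALSE)
  }
  if (any(!is.finite(depth_m)) || any(depth_m <= 0)) {
    stop("fit_martin_b: depths must be positive and finite", call. = FALSE)
  }
  if (is.null(z0)) z0 <- min(depth_m)
  keep <- is.finite(f_total) & f_total > 0
  n_excl <- sum(!keep)
  if (sum(keep) == 0) {
    stop("fit_martin_b: all fluxes are non-positive; profile unfittable",
         call. = FALSE)
  }
  if (sum(keep) < 3) {
    stop("fit_martin_b: fewer than 3 positive-flux points; profile unfittable",
         call. = FALSE)
  }
  x <- log(depth_m[keep] / z0)
  y <- log(f_total[keep])
  w <- NULL
  if (weighted) {
    if (is.null(sd_f_total)) {
      stop("fit_martin_b: weighted fit needs sd_f_total", call. = FALSE)
    }
    sdy <- sd_f_total[keep] / f_total[keep]
    if (any(!is.finite(sdy)) || any(sdy <= 0)) {
      stop("fit_martin_b: weighted fit needs positive finite sd for every point",
           call. = FALSE)
    }
    w <- 1 / sdy^2
  }
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  # exact power-law profiles fit with zero residual; summary.lm warns then
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  # zero-residual (exact power law) profiles: summary reports NaN se
  se <- cf[, "Std. Error"]
  se[!is.finite(se)] <- 0
  r2 <- sm$r.squared
  structure(
    list(b = unname(-cf["x", "Estimate"]),
         b_se = unname(se["x"]),
         ln_f0 = unname(cf["(Intercept)", "Estimate"]),
         ln_f0_se = unname(se["(Intercept)"]),
         z0 = z0,
         n_points = sum(keep),
         n_excluded_nonpositive = n_excl,
         r_squared = if (is.finite(r2)) r2 else 1,
         df_residual = fit$df.residual,
         scheme = scheme),
    class = "martin_fit"
  )
}

#' @export
print.martin_fit <- function(x, ...) {
  cat(sprintf("Martin power-law attenuation fit (%s)\n", x$scheme))
  cat(sprintf("  b = %.4f +/- %.4f   F0 = %.4g (z0 = %g m)\n",
              x$b, x$b_se, exp(x$ln_f0), x$z0))
  cat(sprintf("  n = %d point(s), %d non-positive excluded, R^2 = %.4f\n",
              x$n_points, x$n_excluded_nonpositive, x$r_squared))
  invisible(x)
}

#' Confidence interval for the attenuation coefficient
#'
#' Standard OLS interval on the log-log slope: `b +/- t(1-(1-level)/2, df) * b_se`
#' with the fit's residual degrees of freedom. With the typical 4-point
#' profile the residual df is 2, so the t quantile is materially wider than
#' the normal 1.96 and is required for nominal coverage.
#'
#' @param object A `martin_fit`.
#' @param parm Ignored (the interval is for `b`).
#' @param level Confidence level, default 0.95.
#' @param ... Ignored.
#' @return Numeric vector `c(lower, upper)` for `b`.
#' @export
confint.martin_fit <- function(object, parm = "b", level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df_residual)
  c(lower = object$b - tq * object$b_se,
    upper = object$b + tq * object$b_se)
}

#' Fit attenuation coefficients for every pooled profile
#'
#' Runs [fit_martin_b()] on each profile of a pooled flux table and returns
#' one row per fittable profile. Profiles flagged unfittable (fewer than 3
#' positive-flux points) are skipped and listed in the `"unfit"` attribute.
#'
#' @param pooled Output of [pool_profiles()].
#' @param scheme,weighted Passed to [fit_martin_b()].
#' @return A data.frame with profile metadata (`profile`, `cruise`,
#'   `station`, `occupation` if present, `substance`) and the fit fields of
#'   [fit_martin_b()].
#' @export
fit_attenuation <- function(pooled, scheme = "fixed_vfast", weighted = FALSE) {
  if (is.null(pooled$profile)) {
    stop("fit_attenuation: input lacks 'profile'; run pool_profiles() first",
         call. = FALSE)
  }
  meta_cols <- intersect(c("profile", "cruise", "station", "occupation",
                           "substance"), names(pooled))
  pieces <- lapply(split(pooled, pooled$profile), function(g) {
    fit <- tryCatch(
      fit_martin_b(g$depth_m, g$f_total, sd_f_total = g$sd_f_total,
                   scheme = scheme, weighted = weighted),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    out <- g[1, meta_cols, drop = FALSE]
    out$b <- fit$b
    out$b_se <- fit$b_se
    out$ln_f0 <- fit$ln_f0
    out$ln_f0_se <- fit$ln_f0_se
    out$z0 <- fit$z0
    out$n_points <- fit$n_points
    out$n_excluded_nonpositive <- fit$n_excluded_nonpositive
    out$r_squared <- fit$r_squared
    out$df_residual <- fit$df_residual
    out$scheme <- fit$scheme
    out
  })
  fitted <- do.call(rbind, Filter(Negate(is.null), pieces))
  if (is.null(fitted)) {
    stop("fit_attenuation: no fittable profiles", call. = FALSE)
  }
  rownames(fitted) <- NULL
  attr(fitted, "unfit") <- setdiff(unique(pooled$profile), fitted$profile)
  fitted
}

#' Sensitivity of attenuation coefficients to the bulk sinking velocity
#'
#' Recomputes fluxes and refits the attenuation coefficient for every
#' velocity in a grid, for every pooled profile. Because the fast flux is
#' linear in `v_fast`, profiles whose flux is entirely slow-sinking, or
#' whose fast share of total flux is depth-invariant, return identical `b`
#' across the grid; the analysis probes how far real profiles are from
#' those regimes.
#'
#' @param partitioned Output of [partition_deployments()].
#' @param geom An [msc_geometry()] object.
#' @param grid Velocities in m d-1; default the configured sensitivity grid.
#' @param rule Pooling rule, see [pool_profiles()].
#' @param config A [vfast_config()].
#' @param clamp_negative_slow Passed to [compute_fluxes()].
#' @return A data.frame of fits keyed by (`profile`, `v_fast`).
#' @export
vfast_sensitivity <- function(partitioned, geom, grid = NULL,
                              rule = "by_station", config = vfast_config(),
                              clamp_negative_slow = FALSE) {
  if (is.null(grid)) grid <- config$sensitivity_grid
  if (length(grid) == 0) {
    stop("vfast_sensitivity: empty velocity grid", call. = FALSE)
  }
  out <- lapply(grid, function(v) {
    fx <- compute_fluxes(partitioned, geom, config = config, v_fast = v,
                         clamp_negative_slow = clamp_negative_slow)
    fits <- fit_attenuation(pool_profiles(fx, rule = rule))
    fits$v_fast <- v
    fits
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attenuation coefficients under depth-varying sinking velocity
#'
#' Tests whether the fitted attenuation coefficient survives a sinking
#' velocity that changes with depth. Each profile is split at the arithmetic
#' midpoint of its shallowest and deepest deployment depths (deployments
#' exactly at the midpoint join the shallow group). Under the `"minimized"`
#' scheme the shallow deployments get the slower velocity and the deep ones
#' the faster (40/60 m d-1 by default), exaggerating fluxes at depth and
#' so reducing the apparent attenuation; `"maximized"` does the opposite.
#'
#' @param partitioned Output of [partition_deployments()].
#' @param geom An [msc_geometry()] object.
#' @param scheme `"minimized"` or `"maximized"`.
#' @param shallow_v,deep_v The velocity pair, m d-1; defaults from `config`.
#' @param rule Pooling rule, see [pool_profiles()].
#' @param config A [vfast_config()].
#' @return A data.frame of fits (as [fit_attenuation()]) with the scheme
#'   recorded on every row.
#' @export
depth_split_b <- function(partitioned, geom,
                          scheme = c("minimized", "maximized"),
                          shallow_v = NULL, deep_v = NULL,
                          rule = "by_station", config = vfast_config()) {
  scheme <- match.arg(scheme)
  if (is.null(shallow_v)) shallow_v <- config$depth_split[["shallow"]]
  if (is.null(deep_v)) deep_v <- config$depth_split[["deep"]]
  keys <- switch(rule,
    by_station = c("cruise", "station"),
    by_occupation = c("cruise", "station", "occupation")
  )
  d <- partitioned
  grp <- do.call(paste, c(lapply(keys, function(k) as.character(d[[k]])),
                          sep = "|"))
  rng <- do.call(rbind, tapply(d$depth_m, grp, range, simplify = FALSE))
  if (any(rng[, 1] == rng[, 2])) {
    stop("depth_split_b: profile(s) with a single deployment depth: ",
         paste(rownames(rng)[rng[, 1] == rng[, 2]], collapse = ", "),
         call. = FALSE)
  }
  mid <- (rng[grp, 1] + rng[grp, 2]) / 2
  is_shallow <- d$depth_m <= mid
  v <- if (scheme == "minimized") {
    ifelse(is_shallow, shallow_v, deep_v)
  } else {
    ifelse(is_shallow, deep_v, shallow_v)
  }
  fx <- compute_fluxes(d, geom, config = config, v_fast = v)
  fits <- fit_attenuation(pool_profiles(fx, rule = rule), scheme = scheme)
  fits$scheme <- scheme
  fits
}
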