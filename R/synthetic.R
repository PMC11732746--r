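#' Ground truth for a simulated MSC campaign
#'
#' Describes the "true" ocean a simulated campaign samples: per-substance
#' power-law flux profiles `F(z) = f0 * (z / z0)^-b` with `z0` the
#' shallowest deployment depth, a slow/fast split of the sinking flux, a
#' suspended background concentration, the bulk sinking velocity of the
#' fast pool, and multiplicative lognormal measurement noise applied to
#' every measured fraction. Defaults emulate a productive Southern Ocean
#' bloom station sampled at MLD+10, MLD+110, 400 and 700 m.
#'
#' @param b_true Named vector of true attenuation exponents per substance.
#' @param f0_true Named vector of true reference fluxes at `z0`
#'   (mg m-2 d-1 for CHL/POC, mmol m-2 d-1 for BSI).
#' @param suspended_background Named vector of suspended concentrations
#'   (ug l-1 / umol l-1), assumed depth-invariant.
#' @param slow_fraction Fraction of sinking flux in the slow pool: a scalar
#'   in `[0, 1]` or a function of depth returning values in `[0, 1]`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise on each measured fraction; `>= 0`.
#' @param depths Deployment depths, m, strictly increasing; default
#'   `c(mld + 10, mld + 110, 400, 700)`.
#' @param mld Mixed-layer depth, m, used only for the default depths.
#' @param v_fast_true True bulk sinking velocity of the fast pool, m d-1.
#' @param cruise,station_prefix Labels written into the generated tables.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(b_true = c(BSI = 1.0, POC = 0.4),
                            f0_true = c(BSI = 5, POC = 200),
                            suspended_background = c(BSI = 0.3, POC = 10),
                            slow_fraction = 0.3,
                            noise_cv = 0.2,
                            depths = NULL,
                            mld = 50,
                            v_fast_true = 40,
                            cruise = "SYN1",
                            station_prefix = "S") {
  if (is.null(depths)) depths <- c(mld + 10, mld + 110, 400, 700)
  subs <- validate_substance(names(b_true))
  names(b_true) <- subs
  if (!identical(sort(names(f0_true)), sort(subs)) ||
      !identical(sort(names(suspended_background)), sort(subs))) {
    stop("synthetic_truth: b_true, f0_true and suspended_background must ",
         "share substance names", call. = FALSE)
  }
  if (any(f0_true <= 0)) {
    stop("synthetic_truth: f0_true must be positive", call. = FALSE)
  }
  if (any(suspended_background < 0)) {
    stop("synthetic_truth: suspended_background must be non-negative",
         call. = FALSE)
  }
  if (any(diff(depths) <= 0) || any(depths <= 0)) {
    stop("synthetic_truth: depths must be strictly increasing and positive",
         call. = FALSE)
  }
  sf <- if (is.function(slow_fraction)) slow_fraction(depths) else
    rep_len(slow_fraction, length(depths))
  if (any(sf < 0) || any(sf > 1)) {
    stop("synthetic_truth: slow_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (noise_cv < 0) {
    stop("synthetic_truth: noise_cv must be non-negative", call. = FALSE)
  }
  if (v_fast_true <= 0) {
    stop("synthetic_truth: v_fast_true must be positive", call. = FALSE)
  }
  structure(
    list(b_true = b_true, f0_true = f0_true[subs],
         suspended_background = suspended_background[subs],
         slow_fraction = sf, noise_cv = noise_cv, depths = depths,
         z0 = min(depths), v_fast_true = v_fast_true, cruise = cruise,
         station_prefix = station_prefix),
    class = "synthetic_truth"
  )
}

# mean-preserving multiplicative lognormal noise with coefficient of
# variation cv: sdlog chosen so the multiplier's CV is exactly cv, meanlog
# = -sdlog^2/2 so its mean is exactly 1
lognormal_multiplier <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Forward-simulate an MSC campaign with known truth
#'
#' For every replicate profile, substance and depth, draws the true total
#' flux from the truth's power law, splits it into slow and fast pools,
#' inverts the partitioning and flux equations exactly to obtain the
#' measured fraction concentrations (top, base, tray, time-zero) that would
#' have produced those pools, then applies independent mean-preserving
#' multiplicative lognormal noise to each measured fraction. With
#' `noise_cv = 0` the pipeline recovers the true fluxes exactly, which is
#' the basis of the package's round-trip tests.
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_profiles Number of replicate profiles (each becomes a station).
#' @param seed Integer seed; the only source of randomness.
#' @param geom An [msc_geometry()] object used for the inversion.
#' @return A list with `concentrations` (long-format table matching the
#'   canonical schema of [read_concentrations()]), `truth` (per depth and
#'   substance: the true pools and fluxes), `geom` and `v_fast_true`.
#' @export
generate_campaign <- function(truth, n_profiles = 1, seed = NULL,
                              geom = msc_geometry()) {
  if (!inherits(truth, "synthetic_truth")) {
    stop("generate_campaign: truth must come from synthetic_truth()",
         call. = FALSE)
  }
  if (n_profiles < 1) {
    stop("generate_campaign: n_profiles must be >= 1", call. = FALSE)
  }
  assert_geometry(geom)
  if (!is.null(seed)) set.seed(as.integer(seed))

  subs <- names(truth$b_true)
  depths <- truth$depths
  nd <- length(depths)
  slow_fac <- slow_flux_factor(geom)
  k_tray <- geom$a_tray_m2 * geom$h_m * 1000 / geom$v_tray_l

  grid <- expand.grid(depth_i = seq_len(nd), substance = subs,
                      profile = seq_len(n_profiles),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  z <- depths[grid$depth_i]
  b <- truth$b_true[grid$substance]
  f0 <- truth$f0_true[grid$substance]
  bg <- truth$suspended_background[grid$substance]
  sf <- truth$slow_fraction[grid$depth_i]

  f_total <- f0 * (z / truth$z0)^(-b)
  f_slow <- sf * f_total
  f_fast <- (1 - sf) * f_total

  # exact inversion of the partitioning and flux relations
  p_slow <- f_slow / slow_fac
  p_fast <- f_fast / truth$v_fast_true
  p_top <- bg
  p_base <- p_top + p_slow * geom$v_msc_l / geom$v_base_l
  p_tray <- p_base + p_fast * k_tray
  p_t0 <- p_top + p_slow + p_fast
  if (any(p_base < 0) || any(p_tray < 0)) {
    stop("generate_campaign: inversion produced a negative fraction ",
         "concentration; increase suspended_background or f0_true, or ",
         "reduce the slow/fast imbalance relative to the geometry",
         call. = FALSE)
  }

  cv <- truth$noise_cv
  n <- nrow(grid)
  meas <- data.frame(
    t0 = p_t0 * lognormal_multiplier(n, cv),
    top = p_top * lognormal_multiplier(n, cv),
    base = p_base * lognormal_multiplier(n, cv),
    tray = p_tray * lognormal_multiplier(n, cv)
  )
  sd_true <- data.frame(t0 = cv * p_t0, top = cv * p_top,
                        base = cv * p_base, tray = cv * p_tray)

  station <- sprintf("%s%03d", truth$station_prefix, grid$profile)
  dep_id <- sprintf("%s_%s_d%02d", truth$cruise, station, grid$depth_i)

  long <- do.call(rbind, lapply(c("t0", "top", "base", "tray"), function(fr) {
    data.frame(
      cruise = truth$cruise, station = station, occupation = "O1",
      deployment_id = dep_id, depth_m = z,
      substance = grid$substance, fraction = fr,
      concentration = meas[[fr]], concentration_sd = sd_true[[fr]],
      v_tray_star_l = NA_real_, flags = "",
      stringsAsFactors = FALSE
    )
  }))
  ord <- order(long$station, long$deployment_id, long$substance,
               match(long$fraction, c("t0", "top", "base", "tray")))
  long <- long[ord, ]
  rownames(long) <- NULL

  ledger <- data.frame(
    cruise = truth$cruise, station = station, occupation = "O1",
    deployment_id = dep_id, profile = grid$profile, depth_m = z,
    substance = grid$substance,
    b_true = unname(b), f0_true = unname(f0), z0 = truth$z0,
    v_fast_true = truth$v_fast_true,
    slow_fraction = sf,
    p_top_true = unname(p_top), p_base_true = unname(p_base),
    p_tray_true = unname(p_tray), p_t0_true = unname(p_t0),
    p_slow_true = unname(p_slow), p_fast_true = unname(p_fast),
    f_slow_true = unname(f_slow), f_fast_true = unname(f_fast),
    f_total_true = unname(f_total),
    stringsAsFactors = FALSE
  )

  list(concentrations = long, truth = ledger, geom = geom,
       v_fast_true = truth$v_fast_true)
}

#' Deterministic fixture for molar-ratio depth-trend tests
#'
#' Builds a noise-free two-substance concentration table whose true
#' total-sinking BSi:POC ratio changes monotonically with depth (decreasing
#' when `b_bsi > b_poc`). A small negative slow pool can be injected at
#' every depth (`negative_slow` is the magnitude of the negative slow flux
#' as a fraction of the total flux; the fast pool is enlarged to keep the
#' total), exercising the negative-concentration handling of
#' [total_sinking_ratio()] without changing the true total flux.
#'
#' @param b_bsi,b_poc True attenuation exponents.
#' @param f0_bsi,f0_poc Reference fluxes at the shallowest depth.
#' @param depths Deployment depths, m.
#' @param negative_slow Non-negative scalar; 0 (default) gives an all
#'   positive fixture.
#' @param geom An [msc_geometry()] object.
#' @return A list with `concentrations` (long table) and `truth` (per depth
#'   and substance true pools and fluxes), as [generate_campaign()].
#' @export
generate_ratio_profile_fixture <- function(b_bsi = 1.2, b_poc = 0.5,
                                           f0_bsi = 5, f0_poc = 200,
                                           depths = c(60, 160, 400, 700),
                                           negative_slow = 0,
                                           geom = msc_geometry()) {
  if (negative_slow < 0) {
    stop("generate_ratio_profile_fixture: negative_slow must be >= 0",
         call. = FALSE)
  }
  sfrac <- if (negative_slow > 0) -negative_slow else 0.3
  truth <- synthetic_truth(
    b_true = c(BSI = b_bsi, POC = b_poc),
    f0_true = c(BSI = f0_bsi, POC = f0_poc),
    suspended_background = c(BSI = 2, POC = 60),
    slow_fraction = if (negative_slow > 0) 0 else sfrac,
    noise_cv = 0, depths = depths, cruise = "SYNR"
  )
  out <- generate_campaign(truth, n_profiles = 1, geom = geom)
  if (negative_slow > 0) {
    # rebuild pools with a signed slow share: F_slow = -eps * F_total,
    # F_fast = (1 + eps) * F_total, bypassing the [0, 1] truth invariant
    tr <- out$truth
    slow_fac <- slow_flux_factor(geom)
    k_tray <- geom$a_tray_m2 * geom$h_m * 1000 / geom$v_tray_l
    tr$slow_fraction <- -negative_slow
    tr$f_slow_true <- -negative_slow * tr$f_total_true
    tr$f_fast_true <- (1 + negative_slow) * tr$f_total_true
    tr$p_slow_true <- tr$f_slow_true / slow_fac
    tr$p_fast_true <- tr$f_fast_true / truth$v_fast_true
    tr$p_base_true <- tr$p_top_true +
      tr$p_slow_true * geom$v_msc_l / geom$v_base_l
    tr$p_tray_true <- tr$p_base_true + tr$p_fast_true * k_tray
    tr$p_t0_true <- tr$p_top_true + tr$p_slow_true + tr$p_fast_true
    if (any(tr$p_base_true < 0)) {
      stop("generate_ratio_profile_fixture: negative_slow too large for the ",
           "suspended background", call. = FALSE)
    }
    lc <- out$concentrations
    key <- paste(lc$deployment_id, lc$substance)
    tkey <- paste(tr$deployment_id, tr$substance)
    for (fr in c("t0", "top", "base", "tray")) {
      col <- paste0("p_", fr, "_true")
      sel <- lc$fraction == fr
      lc$concentration[sel] <- tr[[col]][match(key[sel], tkey)]
    }
    out$concentrations <- lc
    out$truth <- tr
  }
  out
}
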