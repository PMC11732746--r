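#' Suspended particle concentration
#'
#' The suspended pool is taken to be the concentration of material remaining
#' in the top of the catcher after the settling period: material that did not
#' sink appreciably in two hours is counted as suspended.
#'
#' @param p_top Top-fraction concentration after settling (ug l-1 for
#'   CHL/POC, umol l-1 for BSI). Vectorized.
#' @param deployment_id Optional identifier(s) used in error messages.
#' @return The suspended concentration, identical to `p_top`, same units.
#' @export
suspended_concentration <- function(p_top, deployment_id = NULL) {
  check_measurement(p_top, "p_top", deployment_id)
  p_top
}

#' Slow-sinking particle concentration
#'
#' Particles that settled out of the water column inside the catcher during
#' the settling period accumulate in the base section. The slow-sinking pool
#' is the base-minus-top concentration difference rescaled by the base to
#' full-catcher volume ratio. The sign is preserved: a base section cleaner
#' than the top yields a negative value, interpreted as an upward flux of
#' material rather than clamped to zero.
#'
#' @param p_top,p_base Top- and base-fraction concentrations, same units.
#'   Vectorized.
#' @param geom An [msc_geometry()] object.
#' @param deployment_id Optional identifier(s) used in error messages.
#' @return `(p_base - p_top) * v_base / v_msc`, in the input units.
#' @examples
#' slow_concentration(1, 2, msc_geometry()) # (2-1) * 8/95
#' @export
slow_concentration <- function(p_top, p_base, geom, deployment_id = NULL) {
  assert_geometry(geom)
  check_measurement(p_top, "p_top", deployment_id)
  check_measurement(p_base, "p_base", deployment_id)
  (p_base - p_top) * geom$v_base_l / geom$v_msc_l
}

#' Fast-sinking particle concentration
#'
#' Fast-sinking particles reach the collection tray at the bottom of the
#' catcher within the settling period. Two measurement variants exist:
#' the standard tray sample, rescaled by tray volume over the water column
#' standing above the tray (`a_tray * h * 1000` litres), and the syphoned
#' variant (`p_tray_star`), where water around the tray was syphoned to give
#' a larger sample volume `v_tray_star_l`, rescaled by that volume over the
#' full catcher volume. Exactly one variant must be supplied per deployment;
#' the variant used is recorded in the result's `method` attribute
#' (`"tray"` or `"tray_star"`).
#'
#' @param p_base Base-fraction concentration. Vectorized.
#' @param p_tray Tray concentration (standard variant), or `NA`.
#' @param p_tray_star Syphoned tray concentration, or `NA`.
#' @param v_tray_star_l Syphoned volume, litres; required with `p_tray_star`.
#' @param geom An [msc_geometry()] object.
#' @param deployment_id Optional identifier(s) used in error messages.
#' @return Fast-sinking concentration in the input units, with attribute
#'   `method` (character vector, `"tray"` or `"tray_star"` per element).
#' @examples
#' fast_concentration(2, p_tray = 10, geom = msc_geometry())
#' @export
fast_concentration <- function(p_base, p_tray = NA_real_,
                               p_tray_star = NA_real_,
                               v_tray_star_l = NA_real_,
                               geom, deployment_id = NULL) {
  assert_geometry(geom)
  check_measurement(p_base, "p_base", deployment_id)
  n <- length(p_base)
  p_tray <- rep_len(p_tray, n)
  p_tray_star <- rep_len(p_tray_star, n)
  v_tray_star_l <- rep_len(v_tray_star_l, n)
  id <- deployment_labels(deployment_id, n)

  has_tray <- !is.na(p_tray)
  has_star <- !is.na(p_tray_star)
  if (any(has_tray & has_star)) {
    stop("ambiguous fast-sinking measurement (both p_tray and p_tray_star) for: ",
         paste(id[has_tray & has_star], collapse = ", "), call. = FALSE)
  }
  if (any(!has_tray & !has_star)) {
    stop("missing fast-sinking measurement (neither p_tray nor p_tray_star) for: ",
         paste(id[!has_tray & !has_star], collapse = ", "), call. = FALSE)
  }
  if (any(has_star & (is.na(v_tray_star_l) | v_tray_star_l <= 0))) {
    stop("p_tray_star requires a positive v_tray_star_l for: ",
         paste(id[has_star & (is.na(v_tray_star_l) | v_tray_star_l <= 0)],
               collapse = ", "), call. = FALSE)
  }

  out <- numeric(n)
  out[has_tray] <- (p_tray[has_tray] - p_base[has_tray]) * geom$v_tray_l /
    (geom$a_tray_m2 * geom$h_m * 1000)
  out[has_star] <- (p_tray_star[has_star] - p_base[has_star]) *
    v_tray_star_l[has_star] / geom$v_msc_l
  attr(out, "method") <- ifelse(has_tray, "tray", "tray_star")
  out
}

#' Partition MSC deployments into suspended, slow and fast pools
#'
#' Applies the suspended/slow/fast decomposition to every row of a wide
#' deployment table (one row per deployment and substance; see
#' [deployments_from_long()]), with first-order propagation of measurement
#' standard deviations assuming independent errors: differences add
#' standard deviations in quadrature, multiplicative constants scale them
#' linearly. Deployments without sd fields get `NA` uncertainties; none are
#' fabricated. Signed (negative) slow and fast pools are preserved.
#'
#' @param deployments Wide deployment data.frame with columns
#'   `deployment_id`, `substance`, `depth_m`, `p_top`, `p_base` and one of
#'   `p_tray` / (`p_tray_star` + `v_tray_star_l`), optional `p_t0` and
#'   matching `sd_*` columns, plus any metadata columns (carried through).
#' @param geom An [msc_geometry()] object.
#' @return The input with columns `p_susp`, `p_slow`, `p_fast`,
#'   `sd_susp`, `sd_slow`, `sd_fast` and `method_fast` appended.
#' @export
partition_deployments <- function(deployments, geom) {
  assert_geometry(geom)
  need <- c("deployment_id", "substance", "depth_m", "p_top", "p_base")
  miss <- setdiff(need, names(deployments))
  if (length(miss) > 0) {
    stop("partition_deployments: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- deployments
  d$substance <- validate_substance(d$substance)
  for (col in c("p_tray", "p_tray_star", "v_tray_star_l",
                "sd_top", "sd_base", "sd_tray", "sd_tray_star")) {
    if (is.null(d[[col]])) d[[col]] <- NA_real_
  }
  id <- paste(d$deployment_id, d$substance, sep = "/")

  d$p_susp <- suspended_concentration(d$p_top, id)
  d$p_slow <- slow_concentration(d$p_top, d$p_base, geom, id)
  pf <- fast_concentration(d$p_base, d$p_tray, d$p_tray_star,
                           d$v_tray_star_l, geom, id)
  d$p_fast <- as.numeric(pf)
  d$method_fast <- attr(pf, "method")

  d$sd_susp <- d$sd_top
  d$sd_slow <- sqrt(d$sd_base^2 + d$sd_top^2) * geom$v_base_l / geom$v_msc_l
  k_tray <- geom$v_tray_l / (geom$a_tray_m2 * geom$h_m * 1000)
  d$sd_fast <- ifelse(
    d$method_fast == "tray",
    sqrt(d$sd_tray^2 + d$sd_base^2) * k_tray,
    sqrt(d$sd_tray_star^2 + d$sd_base^2) * d$v_tray_star_l / geom$v_msc_l
  )
  d
}

check_measurement <- function(x, what, deployment_id = NULL) {
  if (any(is.na(x))) {
    id <- deployment_labels(deployment_id, length(x))
    stop("missing measurement ", what, " for deployment(s): ",
         paste(id[is.na(x)], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

deployment_labels <- function(deployment_id, n) {
  if (is.null(deployment_id)) {
    as.character(seq_len(n))
  } else {
    rep_len(as.character(deployment_id), n)
  }
}
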