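#' Parameters for projecting fluxes below the deepest measurement
#'
#' Describes one of the two deep-flux models used to extend a fitted
#' profile: the power law `F(z) = F_anchor * (z / z_anchor)^-b` (the fitted
#' attenuation curve continued downward) or the exponential
#' `F(z) = F_anchor * exp(-(z - z_anchor) / length_scale)`, where
#' `length_scale` is the remineralization length scale (the depth interval
#' over which the flux falls by a factor e). The exponential is measured in
#' depth below the anchor so both models are continuous at the anchor; set
#' `absolute_z = TRUE` to use absolute depth in the exponent instead
#' (`F(z) = F_anchor * exp(-z / length_scale)`, which is discontinuous at
#' the anchor and kept only for comparison).
#'
#' @param model `"power_law"` or `"exponential"`.
#' @param anchor_depth Depth of the anchor, m (e.g. 750).
#' @param anchor_flux Flux at the anchor; strictly positive.
#' @param b Attenuation exponent (power law).
#' @param length_scale Remineralization length scale, m (exponential);
#'   strictly positive.
#' @param absolute_z See above; default `FALSE`.
#' @return An object of class `projection_params`.
#' @export
projection_params <- function(model = c("power_law", "exponential"),
                              anchor_depth, anchor_flux,
                              b = NULL, length_scale = NULL,
                              absolute_z = FALSE) {
  model <- match.arg(model)
  if (!is.finite(anchor_depth) || anchor_depth <= 0) {
    stop("projection_params: anchor_depth must be positive", call. = FALSE)
  }
  if (!is.finite(anchor_flux) || anchor_flux <= 0) {
    stop("projection_params: anchor_flux must be positive", call. = FALSE)
  }
  if (model == "power_law") {
    if (is.null(b) || !is.finite(b)) {
      stop("projection_params: power_law model needs b", call. = FALSE)
    }
  } else {
    if (is.null(length_scale) || !is.finite(length_scale) ||
        length_scale <= 0) {
      stop("projection_params: exponential model needs a positive length_scale",
           call. = FALSE)
    }
  }
  structure(
    list(model = model, anchor_depth = anchor_depth,
         anchor_flux = anchor_flux, b = b, length_scale = length_scale,
         absolute_z = absolute_z),
    class = "projection_params"
  )
}

#' Project a flux profile to depth
#'
#' Evaluates the deep-flux model of a [projection_params()] object on a
#' depth grid at or below the anchor.
#'
#' @param params A [projection_params()] object.
#' @param depths Depths, m; every depth must be `>= anchor_depth`.
#' @return A data.frame with columns `depth_m` and `flux`.
#' @examples
#' p <- projection_params("power_law", 750, 10, b = 1)
#' project_flux(p, c(750, 1500)) # flux halves when depth doubles
#' @export
project_flux <- function(params, depths) {
  if (!inherits(params, "projection_params")) {
    stop("project_flux: params must come from projection_params()",
         call. = FALSE)
  }
  if (any(!is.finite(depths)) || any(depths < params$anchor_depth)) {
    stop("project_flux: all depths must be finite and >= anchor_depth",
         call. = FALSE)
  }
  flux <- if (params$model == "power_law") {
    params$anchor_flux * (depths / params$anchor_depth)^(-params$b)
  } else if (params$absolute_z) {
    params$anchor_flux * exp(-depths / params$length_scale)
  } else {
    params$anchor_flux * exp(-(depths - params$anchor_depth) /
                               params$length_scale)
  }
  data.frame(depth_m = depths, flux = flux)
}

#' Projected deep BSi:POC molar-ratio profile
#'
#' Evaluates the projected BSi and POC fluxes on a shared depth grid and
#' returns their elementwise molar ratio, converting the POC flux from mass
#' to molar units (mg to mmol via the molar mass of carbon) first. Under
#' the power law with `b_BSi > b_POC` the ratio decreases strictly with
#' depth; under exponentials it moves with the sign of the length-scale
#' difference.
#'
#' @param bsi_params,poc_params [projection_params()] for each substance
#'   (fluxes in mmol m-2 d-1 for BSi; POC in mg m-2 d-1 unless
#'   `poc_unit = "molar"`).
#' @param depths Shared depth grid, m; each `>=` both anchors.
#' @param poc_unit `"mass"` (default; converted internally) or `"molar"`.
#' @return A data.frame with `depth_m`, `flux_bsi`, `flux_poc_mmol`,
#'   `ratio` (mol mol-1).
#' @export
projected_ratio_profile <- function(bsi_params, poc_params, depths,
                                    poc_unit = c("mass", "molar")) {
  poc_unit <- match.arg(poc_unit)
  bsi <- project_flux(bsi_params, depths)
  poc <- project_flux(poc_params, depths)
  poc_mmol <- if (poc_unit == "mass") poc_mass_to_mol(poc$flux) else poc$flux
  if (any(poc_mmol <= 0)) {
    stop("projected_ratio_profile: POC flux non-positive at depth(s) ",
         paste(depths[poc_mmol <= 0], collapse = ", "),
         "; ratio undefined", call. = FALSE)
  }
  data.frame(depth_m = depths, flux_bsi = bsi$flux, flux_poc_mmol = poc_mmol,
             ratio = bsi$flux / poc_mmol)
}

#' Projection parameters from a fitted attenuation curve
#'
#' Anchors a power-law projection on a [fit_martin_b()] fit: the anchor flux
#' is the fitted curve evaluated at `anchor_depth`, and the exponent is the
#' fitted `b`, so the projection continues the fitted curve exactly.
#'
#' @param fit A `martin_fit`.
#' @param anchor_depth Anchor depth, m; defaults to the fit's `z0`.
#' @return A [projection_params()] object.
#' @export
projection_from_fit <- function(fit, anchor_depth = NULL) {
  if (!inherits(fit, "martin_fit")) {
    stop("projection_from_fit: fit must be a martin_fit", call. = FALSE)
  }
  if (is.null(anchor_depth)) anchor_depth <- fit$z0
  anchor_flux <- exp(fit$ln_f0) * (anchor_depth / fit$z0)^(-fit$b)
  projection_params("power_law", anchor_depth, anchor_flux, b = fit$b)
}
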