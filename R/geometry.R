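#' Marine snow catcher geometry
#'
#' Instrument constants for a marine snow catcher (MSC): a large closing
#' water sampler that is left to stand on deck so that sinking particles
#' settle into a base section and a collection tray. These constants
#' parameterize the partitioning of measured fraction concentrations into
#' suspended, slow-sinking and fast-sinking pools and the conversion of
#' pools to fluxes.
#'
#' The catcher cross-sectional area `a_msc_m2` is normally derived from the
#' full volume and height assuming a vertical cylinder,
#' `a_msc = v_msc / (h * 1000)` (the 1000 converts litres to cubic metres).
#' It can be supplied explicitly, in which case it must agree with the
#' derived value to 1e-9 relative tolerance.
#'
#' @param v_msc_l Volume of the full catcher, litres. Default 95.
#' @param v_base_l Volume of the base section, litres. Default 8.
#' @param v_tray_l Volume of the particle collection tray, litres.
#'   Default 1 (the nominal tray volume is approximate; override if the
#'   tray was measured).
#' @param a_tray_m2 Tray collection area, m^2. Default 0.026.
#' @param h_m Height of the catcher, m. Default 1.58.
#' @param t_settle_h Settling period, hours. Default 2. Stored internally
#'   in days (`t_settle_d`) because fluxes are per day.
#' @param a_msc_m2 Optional explicit cross-sectional area, m^2.
#'
#' @return An object of class `msc_geometry`: a list with the fields above
#'   plus the derived `a_msc_m2` and `t_settle_d`.
#' @examples
#' geom <- msc_geometry()
#' geom$a_msc_m2 # 95 l / (1.58 m * 1000 l/m^3) = 0.0601 m^2
#' @export
msc_geometry <- function(v_msc_l = 95, v_base_l = 8, v_tray_l = 1,
                         a_tray_m2 = 0.026, h_m = 1.58, t_settle_h = 2,
                         a_msc_m2 = NULL) {
  num <- c(v_msc_l = v_msc_l, v_base_l = v_base_l, v_tray_l = v_tray_l,
           a_tray_m2 = a_tray_m2, h_m = h_m, t_settle_h = t_settle_h)
  bad <- !is.finite(num) | num <= 0
  if (any(bad)) {
    stop("msc_geometry: fields must be strictly positive and finite: ",
         paste(names(num)[bad], collapse = ", "), call. = FALSE)
  }
  if (v_base_l >= v_msc_l) {
    stop("msc_geometry: v_base_l must be smaller than v_msc_l", call. = FALSE)
  }
  if (v_tray_l >= v_base_l) {
    stop("msc_geometry: v_tray_l must be smaller than v_base_l", call. = FALSE)
  }
  a_derived <- v_msc_l / (h_m * 1000)
  if (is.null(a_msc_m2)) {
    a_msc_m2 <- a_derived
  } else {
    if (!is.finite(a_msc_m2) || a_msc_m2 <= 0) {
      stop("msc_geometry: a_msc_m2 must be strictly positive", call. = FALSE)
    }
    if (abs(a_msc_m2 - a_derived) > 1e-9 * a_derived) {
      stop(sprintf(
        "msc_geometry: supplied a_msc_m2 (%.8g) inconsistent with v_msc_l / (h_m * 1000) = %.8g",
        a_msc_m2, a_derived), call. = FALSE)
    }
  }
  structure(
    list(v_msc_l = v_msc_l, v_base_l = v_base_l, v_tray_l = v_tray_l,
         a_tray_m2 = a_tray_m2, h_m = h_m, t_settle_h = t_settle_h,
         t_settle_d = t_settle_h / 24, a_msc_m2 = a_msc_m2),
    class = "msc_geometry"
  )
}

#' @export
print.msc_geometry <- function(x, ...) {
  cat("Marine snow catcher geometry\n")
  cat(sprintf("  V_MSC  = %g l   V_base = %g l   V_tray = %g l\n",
              x$v_msc_l, x$v_base_l, x$v_tray_l))
  cat(sprintf("  A_tray = %g m^2   A_MSC = %.5g m^2 (derived)   h = %g m\n",
              x$a_tray_m2, x$a_msc_m2, x$h_m))
  cat(sprintf("  settling period = %g h\n", x$t_settle_h))
  invisible(x)
}

assert_geometry <- function(geom) {
  if (!inherits(geom, "msc_geometry")) {
    stop("expected an 'msc_geometry' object; see msc_geometry()", call. = FALSE)
  }
  geom
}

#' Concentration and flux units for a substance
#'
#' The unit registry keyed by substance. Chlorophyll-a (CHL) and particulate
#' organic carbon (POC) concentrations are in micrograms per litre and their
#' fluxes in mg m^-2 d^-1; biogenic silica (BSI) is measured in molar units,
#' micromoles per litre and mmol m^-2 d^-1. Operations never convert between
#' substances' units silently.
#'
#' @param substance Character vector with elements from `"CHL"`, `"POC"`,
#'   `"BSI"`.
#' @return A data.frame with columns `substance`, `conc_unit`, `flux_unit`.
#' @export
substance_units <- function(substance) {
  substance <- validate_substance(substance)
  molar <- substance == "BSI"
  data.frame(
    substance = substance,
    conc_unit = ifelse(molar, "umol l-1", "ug l-1"),
    flux_unit = ifelse(molar, "mmol m-2 d-1", "mg m-2 d-1"),
    stringsAsFactors = FALSE
  )
}

SUBSTANCES <- c("CHL", "POC", "BSI")

validate_substance <- function(substance) {
  substance <- toupper(as.character(substance))
  unknown <- setdiff(unique(substance), SUBSTANCES)
  if (length(unknown) > 0) {
    stop("unknown substance(s): ", paste(unknown, collapse = ", "),
         " (expected CHL, POC or BSI)", call. = FALSE)
  }
  substance
}
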