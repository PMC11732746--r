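CONC_COLUMNS <- c("cruise", "station", "occupation", "deployment_id",
                  "depth_m", "substance", "fraction", "concentration",
                  "concentration_sd", "v_tray_star_l", "flags")
FRACTIONS <- c("t0", "top", "base", "tray", "tray_star")

#' Read a long-format MSC concentration table
#'
#' The canonical interchange format is a tidy CSV with one row per measured
#' fraction: columns `cruise`, `station`, `occupation`, `deployment_id`,
#' `depth_m`, `substance` (CHL/POC/BSI), `fraction` (t0/top/base/tray/
#' tray_star), `concentration`, and optional `concentration_sd`,
#' `v_tray_star_l`, `flags` (semicolon-separated). Units are implied by the
#' substance (ug l-1 for CHL/POC, umol l-1 for BSI).
#'
#' Structural defects (duplicate `(deployment_id, substance, fraction)`
#' keys, unknown substances) are hard errors naming the offenders.
#' Malformed rows (non-positive or missing depth, missing concentration,
#' unknown fraction, `tray_star` without a syphoned volume) are collected
#' into a rejects table attached as the `"rejects"` attribute, with a
#' warning; they are never silently dropped.
#'
#' @param path CSV file path.
#' @return The validated long-format data.frame (possibly empty, with a
#'   warning) with attribute `"rejects"`.
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) {
    stop("read_concentrations: no such file: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_concentrations(raw, context = path)
}

#' Validate an in-memory long-format concentration table
#'
#' The validation backend of [read_concentrations()]; useful when the table
#' was built programmatically (e.g. by [generate_campaign()]).
#'
#' @param x A data.frame in the canonical long layout.
#' @param context Label used in messages.
#' @return As [read_concentrations()].
#' @export
validate_concentrations <- function(x, context = "concentrations") {
  need <- c("cruise", "station", "deployment_id", "depth_m", "substance",
            "fraction", "concentration")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("validate_concentrations: ", context, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(CONC_COLUMNS, names(x))) {
    x[[col]] <- if (col %in% c("concentration_sd", "v_tray_star_l"))
      NA_real_ else ""
  }
  x <- x[CONC_COLUMNS]
  # CSV round trips: all-empty columns come back logical; restore types
  for (col in c("depth_m", "concentration", "concentration_sd",
                "v_tray_star_l")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  for (col in c("cruise", "station", "occupation", "deployment_id",
                "substance", "fraction", "flags")) {
    x[[col]] <- as.character(x[[col]])
    x[[col]][is.na(x[[col]])] <- ""
  }
  if (nrow(x) == 0) {
    warning("validate_concentrations: ", context, " has no data rows",
            call. = FALSE)
    attr(x, "rejects") <- x[0, ]
    return(x)
  }
  x$substance <- validate_substance(x$substance)
  key <- paste(x$deployment_id, x$substance, x$fraction, sep = "/")
  if (anyDuplicated(key)) {
    stop("validate_concentrations: duplicate (deployment_id, substance, ",
         "fraction) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  reason <- rep("", nrow(x))
  bad_depth <- !is.finite(x$depth_m) | x$depth_m <= 0
  reason[bad_depth] <- "non-positive or missing depth_m"
  bad_frac <- !(x$fraction %in% FRACTIONS)
  reason[bad_frac] <- "unknown fraction"
  bad_conc <- !bad_frac & !bad_depth & !is.finite(x$concentration)
  reason[bad_conc] <- "missing concentration"
  bad_star <- x$fraction == "tray_star" &
    (!is.finite(x$v_tray_star_l) | x$v_tray_star_l <= 0)
  reason[bad_star & reason == ""] <- "tray_star without v_tray_star_l"
  rejects <- x[reason != "", , drop = FALSE]
  if (nrow(rejects) > 0) {
    rejects$reject_reason <- reason[reason != ""]
    warning("validate_concentrations: rejected ", nrow(rejects),
            " malformed row(s); see attr(x, 'rejects')", call. = FALSE)
  } else {
    rejects$reject_reason <- character(0)
  }
  out <- x[reason == "", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Reshape a long concentration table to one row per deployment
#'
#' Pivots the canonical long layout to the wide layout consumed by
#' [partition_deployments()]: one row per `(deployment_id, substance)` with
#' `p_t0`, `p_top`, `p_base`, `p_tray`, `p_tray_star` and matching `sd_*`
#' columns.
#'
#' @param long Output of [read_concentrations()].
#' @return A wide data.frame.
#' @export
deployments_from_long <- function(long) {
  keys <- c("cruise", "station", "occupation", "deployment_id", "depth_m",
            "substance")
  key <- do.call(paste, c(long[keys], sep = "\r"))
  pieces <- lapply(split(long, key), function(g) {
    out <- g[1, keys, drop = FALSE]
    for (fr in FRACTIONS) {
      row <- g[g$fraction == fr, , drop = FALSE]
      cn <- if (fr == "t0") "p_t0" else paste0("p_", fr)
      sn <- if (fr == "t0") "sd_t0" else paste0("sd_", fr)
      out[[cn]] <- if (nrow(row) == 1) row$concentration else NA_real_
      out[[sn]] <- if (nrow(row) == 1) row$concentration_sd else NA_real_
    }
    star <- g[g$fraction == "tray_star", , drop = FALSE]
    out$v_tray_star_l <- if (nrow(star) == 1) star$v_tray_star_l else NA_real_
    out$flags <- paste(unique(g$flags[g$flags != ""]), collapse = ";")
    out
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$station, out$deployment_id, out$substance), ]
  rownames(out) <- NULL
  out
}

#' Reshape a wide deployment table back to the canonical long layout
#'
#' Inverse of [deployments_from_long()] for the measured fractions.
#'
#' @param wide A wide deployment data.frame.
#' @return A long-format data.frame in the canonical column order.
#' @export
deployments_to_long <- function(wide) {
  pieces <- lapply(FRACTIONS, function(fr) {
    cn <- if (fr == "t0") "p_t0" else paste0("p_", fr)
    sn <- if (fr == "t0") "sd_t0" else paste0("sd_", fr)
    if (is.null(wide[[cn]])) return(NULL)
    sel <- is.finite(wide[[cn]])
    if (!any(sel)) return(NULL)
    data.frame(
      cruise = wide$cruise[sel], station = wide$station[sel],
      occupation = wide$occupation[sel],
      deployment_id = wide$deployment_id[sel], depth_m = wide$depth_m[sel],
      substance = wide$substance[sel], fraction = fr,
      concentration = wide[[cn]][sel],
      concentration_sd = if (is.null(wide[[sn]])) NA_real_ else
        wide[[sn]][sel],
      v_tray_star_l = if (fr == "tray_star") wide$v_tray_star_l[sel] else
        NA_real_,
      flags = if (is.null(wide$flags)) "" else wide$flags[sel],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), pieces))
  ord <- order(out$station, out$deployment_id, out$substance,
               match(out$fraction, FRACTIONS))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Write a table to CSV
#'
#' Numeric columns are written with 6 significant digits by default; pass
#' `full_precision = TRUE` to write at full double precision (needed when
#' byte-identical round trips matter).
#'
#' @param x A data.frame.
#' @param path Output CSV path.
#' @param digits Significant digits, default 6.
#' @param full_precision Write full precision, ignoring `digits`.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, digits = 6, full_precision = FALSE) {
  out <- x
  if (!full_precision) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = digits)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
write_concentrations <- function(x, path, digits = 6,
                                 full_precision = FALSE) {
  write_table_csv(as.data.frame(x)[intersect(CONC_COLUMNS, names(x))],
                  path, digits, full_precision)
}

#' Read a flux table written by [write_table_csv()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_fluxes <- function(path) {
  if (!file.exists(path)) {
    stop("read_fluxes: no such file: ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Import supplementary-style concentration and flux sheets
#'
#' Convenience adapter for tables laid out like a cruise supplementary
#' workbook, with one CSV file per sheet (export each sheet to CSV first).
#' Headers are matched fuzzily — case, spacing and punctuation are ignored,
#' and common synonyms (`depth`, `depth (m)`, `event`, `sd`, ...) are
#' recognised — and an explicit `mapping` (named character vector
#' `c(canonical = "header as printed")`) overrides the fuzzy match. Extra
#' columns are ignored with a message. An unrecognised layout is an error
#' naming the first canonical column that could not be matched.
#'
#' @param concentrations_csv Path to the concentrations sheet (CSV).
#' @param fluxes_csv Optional path to the fluxes sheet (CSV).
#' @param mapping Optional named character vector of header overrides.
#' @return A list with `concentrations` (validated long table, see
#'   [read_concentrations()]) and `fluxes` (normalised data.frame or
#'   `NULL`).
#' @export
import_supplementary_tables <- function(concentrations_csv,
                                        fluxes_csv = NULL, mapping = NULL) {
  conc_raw <- utils::read.csv(concentrations_csv, stringsAsFactors = FALSE,
                              check.names = FALSE)
  conc <- normalize_headers(conc_raw, CONC_COLUMNS,
                            required = c("station", "deployment_id",
                                         "depth_m", "substance", "fraction",
                                         "concentration"),
                            mapping = mapping, context = concentrations_csv)
  if (is.null(conc$cruise)) conc$cruise <- "UNKNOWN"
  conc <- validate_concentrations(conc, context = concentrations_csv)

  fluxes <- NULL
  if (!is.null(fluxes_csv)) {
    flux_raw <- utils::read.csv(fluxes_csv, stringsAsFactors = FALSE,
                                check.names = FALSE)
    flux_cols <- c("cruise", "station", "occupation", "deployment_id",
                   "depth_m", "substance", "f_slow", "f_fast", "f_total")
    fluxes <- normalize_headers(flux_raw, flux_cols,
                                required = c("station", "depth_m",
                                             "substance", "f_total"),
                                mapping = mapping, context = fluxes_csv)
    units <- substance_units(fluxes$substance)
    fluxes$flux_unit <- units$flux_unit
  }
  list(concentrations = conc, fluxes = fluxes)
}

# fuzzy header matcher: squash case and punctuation, then try synonyms
normalize_headers <- function(x, canonical, required, mapping = NULL,
                              context = "sheet") {
  squash <- function(s) gsub("[^a-z0-9]", "", tolower(s))
  syn <- list(
    depth_m = c("depth", "depthm", "deploymentdepth", "deploymentdepthm"),
    deployment_id = c("deployment", "event", "eventid", "msc", "mscid"),
    concentration = c("conc", "concentrationugl", "concentrationumoll",
                      "value"),
    concentration_sd = c("sd", "stdev", "concentrationsd", "uncertainty"),
    v_tray_star_l = c("vtraystar", "vtraystarl", "syphonedvolume",
                      "syphonedvolumel"),
    f_slow = c("slowflux", "fslow", "slowsinkingflux"),
    f_fast = c("fastflux", "ffast", "fastsinkingflux"),
    f_total = c("totalflux", "ftotal"),
    substance = c("parameter", "compound", "variable"),
    occupation = c("occ", "visit"),
    fraction = c("particlefraction", "frac")
  )
  have <- squash(names(x))
  out <- list()
  matched_src <- character(0)
  for (cn in canonical) {
    src <- NA_integer_
    if (!is.null(mapping) && cn %in% names(mapping)) {
      src <- match(squash(mapping[[cn]]), have)
    }
    if (is.na(src)) src <- match(squash(cn), have)
    if (is.na(src) && cn %in% names(syn)) {
      hits <- match(syn[[cn]], have)
      hits <- hits[!is.na(hits)]
      if (length(hits) > 0) src <- hits[1]
    }
    if (!is.na(src)) {
      out[[cn]] <- x[[src]]
      matched_src <- c(matched_src, names(x)[src])
    } else if (cn %in% required) {
      stop("import: could not match required column '", cn, "' in ",
           context, " (headers: ", paste(names(x), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  extra <- setdiff(names(x), matched_src)
  if (length(extra) > 0) {
    message("import: ignoring unmatched column(s) in ", context, ": ",
            paste(extra, collapse = ", "))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Cross-validate an imported flux sheet against recomputed fluxes
#'
#' Recomputes slow/fast/total fluxes from an imported concentration table
#' and reports the relative difference against the fluxes printed in the
#' imported flux sheet, row by row. No tolerance is asserted; the report is
#' for audit.
#'
#' @param concentrations Validated long concentration table.
#' @param fluxes Normalised flux sheet (from
#'   [import_supplementary_tables()]).
#' @param geom An [msc_geometry()] object.
#' @param config A [vfast_config()].
#' @return A data.frame with the sheet fluxes, recomputed fluxes and
#'   `rel_diff_total`.
#' @export
crossvalidate_fluxes <- function(concentrations, fluxes,
                                 geom = msc_geometry(),
                                 config = vfast_config()) {
  wide <- deployments_from_long(concentrations)
  parts <- partition_deployments(wide, geom)
  recomputed <- compute_fluxes(parts, geom, config = config)
  keys <- intersect(c("deployment_id", "substance"), names(fluxes))
  m <- merge(fluxes, recomputed[c(keys, "f_total")],
             by = keys, suffixes = c("_sheet", "_recomputed"))
  m$rel_diff_total <- (m$f_total_sheet - m$f_total_recomputed) /
    abs(m$f_total_recomputed)
  m
}
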