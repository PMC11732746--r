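# standard atomic weight of carbon, g mol-1
CARBON_MOLAR_MASS <- 12.011

#' Convert particulate organic carbon from mass to molar concentration
#'
#' POC is measured in mass units (ug l-1) while biogenic silica is measured
#' in molar units, so computing BSi:POC molar ratios requires dividing POC
#' by the molar mass of carbon (12.011 g mol-1).
#'
#' @param poc POC concentration in ug l-1 (or flux in mg m-2 d-1; the same
#'   factor converts to mmol m-2 d-1). Vectorized.
#' @return The molar equivalent, umol l-1 (or mmol m-2 d-1).
#' @examples
#' poc_mass_to_mol(12.011) # 1 umol l-1
#' @export
poc_mass_to_mol <- function(poc) {
  poc / CARBON_MOLAR_MASS
}

#' BSi:POC molar ratio of total sinking material
#'
#' Sums the slow- and fast-sinking pools of each substance before taking the
#' ratio. Where a slow-sinking concentration is negative (an upward flux of
#' material, typically a small noise artefact), its magnitude is added to
#' the fast-sinking concentration rather than subtracted
#' (`negative_rule = "magnitude"`, the default); `negative_rule = "drop"`
#' instead contributes zero for negative slow pools, which is useful for
#' checking that depth trends do not depend on the handling of negatives.
#'
#' @param bsi_slow,bsi_fast BSi pools, umol l-1. Vectorized.
#' @param poc_slow,poc_fast POC pools, ug l-1.
#' @param negative_rule `"magnitude"` or `"drop"`; how negative slow pools
#'   enter the sums.
#' @return BSi:POC molar ratio, mol mol-1. `NaN` (with a warning) where the
#'   denominator is not positive after the rule is applied; such records are
#'   flagged, never silently dropped.
#' @examples
#' total_sinking_ratio(0.5, 0.5, 12.011, 12.011) # 0.5 mol mol-1
#' @export
total_sinking_ratio <- function(bsi_slow, bsi_fast, poc_slow, poc_fast,
                                negative_rule = c("magnitude", "drop")) {
  negative_rule <- match.arg(negative_rule)
  num <- sum_sinking_pools(bsi_slow, bsi_fast, negative_rule)
  den <- poc_mass_to_mol(sum_sinking_pools(poc_slow, poc_fast, negative_rule))
  bad <- !is.na(den) & den <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive POC denominator; ",
            "ratio undefined (NaN)", call. = FALSE)
    den[bad] <- NA_real_
  }
  out <- num / den
  out[bad] <- NaN
  out
}

sum_sinking_pools <- function(slow, fast, negative_rule) {
  slow_part <- switch(negative_rule,
    magnitude = abs(slow),
    drop = pmax(slow, 0)
  )
  # the rule only rewrites negative slow pools; positive ones pass through
  ifelse(slow < 0, slow_part + fast, slow + fast)
}

#' Per-deployment BSi:POC molar ratios
#'
#' Pairs the BSI and POC rows of a partitioned deployment table by
#' deployment and computes molar ratios for the requested particulate
#' fractions: `time_zero` (total water at closure, from `p_t0`),
#' `suspended`, `slow`, `fast` (each per-pool, no negative-handling rule,
#' negative results flagged) and `total_sinking` (slow+fast with the
#' magnitude rule of [total_sinking_ratio()]).
#'
#' @param partitioned Output of [partition_deployments()] containing both
#'   BSI and POC rows for the deployments of interest.
#' @param fractions Character vector of fractions to compute.
#' @param negative_rule Passed to [total_sinking_ratio()].
#' @return A data.frame of molar-ratio records: deployment metadata,
#'   `fraction`, `ratio` (mol mol-1) and `flag`
#'   (`""`, `"negative_ratio"` or `"undefined_ratio"`).
#' @export
molar_ratios <- function(partitioned,
                         fractions = c("time_zero", "suspended", "slow",
                                       "fast", "total_sinking"),
                         negative_rule = "magnitude") {
  fractions <- match.arg(fractions, several.ok = TRUE)
  d <- partitioned
  keys <- intersect(c("cruise", "station", "occupation", "deployment_id",
                      "depth_m"), names(d))
  if (!"deployment_id" %in% keys) {
    stop("molar_ratios: input needs a deployment_id column", call. = FALSE)
  }
  take <- function(sub) {
    x <- d[d$substance == sub,
           c(keys, intersect(c("p_t0", "p_susp", "p_slow", "p_fast"),
                             names(d))),
           drop = FALSE]
    names(x)[-seq_along(keys)] <- paste0(tolower(sub), "_",
                                         names(x)[-seq_along(keys)])
    x
  }
  m <- merge(take("BSI"), take("POC"), by = keys, sort = FALSE)
  if (nrow(m) == 0) {
    stop("molar_ratios: no deployments with both BSI and POC measurements",
         call. = FALSE)
  }

  one_fraction <- function(frac) {
    if (frac == "total_sinking") {
      ratio <- suppressWarnings(total_sinking_ratio(
        m$bsi_p_slow, m$bsi_p_fast, m$poc_p_slow, m$poc_p_fast,
        negative_rule = negative_rule))
      flag <- ifelse(is.nan(ratio), "undefined_ratio", "")
    } else {
      col <- switch(frac, time_zero = "p_t0", suspended = "p_susp",
                    slow = "p_slow", fast = "p_fast")
      num <- m[[paste0("bsi_", col)]]
      den <- m[[paste0("poc_", col)]]
      if (is.null(num) || is.null(den)) {
        return(NULL)
      }
      den_mol <- poc_mass_to_mol(den)
      ratio <- ifelse(!is.na(den_mol) & den_mol != 0, num / den_mol, NaN)
      flag <- ifelse(is.nan(ratio), "undefined_ratio",
                     ifelse(ratio < 0, "negative_ratio", ""))
    }
    cbind(m[keys], data.frame(fraction = frac, ratio = ratio, flag = flag,
                              stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, Filter(Negate(is.null), lapply(fractions, one_fraction)))
  rownames(out) <- NULL
  out
}

#' Aggregate molar-ratio records
#'
#' Arithmetic mean and sample (n-1) standard deviation of ratios per group,
#' weighting deployments equally. Groups whose ratios are all missing are
#' skipped with a message.
#'
#' @param records Output of [molar_ratios()] (or any data.frame with a
#'   `ratio` column).
#' @param by Character vector of grouping columns present in `records`.
#' @return A data.frame with the grouping columns, `ratio` (mean), `sd`
#'   (`NA` for single-deployment groups) and `n_deployments`.
#' @examples
#' recs <- data.frame(station = "P3", depth_m = 500,
#'                    fraction = "total_sinking", ratio = c(0.2, 0.4))
#' aggregate_ratios(recs, by = c("station", "depth_m", "fraction"))
#' @export
aggregate_ratios <- function(records,
                             by = c("station", "occupation", "depth_m",
                                    "fraction")) {
  if (nrow(records) == 0) {
    stop("aggregate_ratios: empty input", call. = FALSE)
  }
  by <- intersect(by, names(records))
  if (length(by) == 0) {
    stop("aggregate_ratios: no grouping columns found", call. = FALSE)
  }
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(records, key), function(g) {
    r <- g$ratio[is.finite(g$ratio)]
    if (length(r) == 0) {
      message("aggregate_ratios: skipping group with no finite ratios (",
              paste(unlist(g[1, by]), collapse = "/"), ")")
      return(NULL)
    }
    out <- g[1, by, drop = FALSE]
    out$ratio <- mean(r)
    out$sd <- if (length(r) > 1) stats::sd(r) else NA_real_
    out$n_deployments <- length(r)
    out
  })
  out <- do.call(rbind, Filter(Negate(is.null), pieces))
  rownames(out) <- NULL
  out
}
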