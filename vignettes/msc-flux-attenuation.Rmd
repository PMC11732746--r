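---
title: "Partitioning marine snow catcher samples and fitting flux attenuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning marine snow catcher samples and fitting flux attenuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscflux)
```

## The measurement model

A marine snow catcher (MSC) is a large (95 l) closing water sampler. After
recovery it stands on deck for a settling period *t* (2 h by default).
Particles that sink fast enough reach a collection tray at the bottom;
particles that sink slowly accumulate in the base section; material still in
the top of the catcher is counted as suspended. Measuring the concentration
of a substance (chlorophyll-a, particulate organic carbon, biogenic silica)
in the top, base and tray fractions therefore separates three particle
pools:

* suspended: `P_susp = P_top`;
* slow-sinking: `P_slow = (P_base - P_top) * V_base / V_MSC`;
* fast-sinking: `P_fast = (P_tray - P_base) * V_tray / (A_tray * h * 1000)`,
  or, for deployments where water was syphoned from around the tray,
  `P_fast = (P_tray* - P_base) * V_tray* / V_MSC`.

The geometry constants (`msc_geometry()`) default to a 95 l catcher with an
8 l base, a ~1 l tray of area 0.026 m², and height 1.58 m; the
cross-sectional area is derived as `V_MSC / (h * 1000)` = 0.0601 m²,
consistent with a vertical cylinder, because it is not measured directly.
All constants are overridable — the tray volume in particular is nominal.

Signed differences are preserved: a base section cleaner than the top gives
a negative slow pool, which we interpret as an upward flux of material
rather than clamping to zero. Downstream consumers decide how to handle the
sign (see the molar-ratio rule below). The time-zero concentration `p_t0`
is carried through as data but the closure `t0 ≈ top + slow + fast` is not
enforced: it involves independently measured samples and is better audited
than asserted.

Fluxes follow from the pools. Slow-sinking material settled through the
catcher height during the settling period, so
`F_slow = P_slow * V_MSC / (A_MSC * t * 1000)` with *t* in days —
numerically the pool concentration (as mg m⁻³) times `h / t` in m d⁻¹.
Fast-sinking fluxes require an assumed bulk sinking velocity:
`F_fast = P_fast * v_fast`. Units are mg m⁻² d⁻¹ for chlorophyll and POC
and mmol m⁻² d⁻¹ for BSi; concentrations are µg l⁻¹ and µmol l⁻¹
respectively, and the operations never convert across substances silently.
The settling time is entered in hours and converted to days internally, so
unit mistakes in the flux denominator cannot arise from configuration.

`v_fast` is the critical tunable. The per-cruise defaults in
`vfast_config()` are 60 m d⁻¹ for the Atlantic cruise (supported by in-situ
sinking-velocity and polonium-derived estimates) and 40 m d⁻¹ for the
Pacific cruise (thorium-derived bulk velocities and nutrient-budget
comparisons); the sensitivity grid is 20, 40, 60 and 100 m d⁻¹. Whatever
velocity a record was converted with is stored on the record for audit.

Measurement standard deviations, where available, propagate to first order
assuming independent errors: differences add in quadrature, constants scale
linearly, and the total-flux sd adds the slow- and fast-flux sds in
quadrature. Deployments without reported uncertainties get `NA`, never a
fabricated value. The slow and fast pools share the base measurement, so
their errors are in truth slightly anticorrelated; the independence
assumption is the standard convention for these instruments and errs
conservative on the total.

## Molar ratios

BSi:POC molar ratios are computed per deployment for the time-zero,
suspended, slow, fast and total-sinking fractions, converting POC mass to
moles with the standard atomic weight of carbon, 12.011 g mol⁻¹. For the
total-sinking fraction the slow and fast pools are summed first; where a
slow pool is negative its magnitude is added to the fast pool rather than
subtracted. The rule is applied only to the total-sinking sum — that is the
only place it is defined — and an alternative `"drop"` rule (negative slow
pools contribute zero) exists purely to check that depth trends do not
depend on the choice; a property test asserts the Spearman sign of the
ratio-depth trend is identical under both rules on fixtures with small
negative slow pools. Aggregation over deployments is an equally weighted
arithmetic mean with a sample (n−1) standard deviation; single-deployment
groups report `NA` rather than zero spread. Ratios with a non-positive POC
denominator are flagged, not dropped.

## Fitting flux attenuation

Flux attenuation is summarised by the power law `F(z) = F0 (z/z0)^-b`, fit
as ordinary least squares of `ln F` on `ln(z/z0)` with an intercept; `b` is
minus the slope and `b_se` its OLS standard error. We fit in log space, not
by nonlinear least squares in flux space, because the reported uncertainty
is the standard error of a linear model and the log fit is exactly
determined and deterministic. The reference depth `z0` is the shallowest
deployment depth actually present in each pooled profile (target depths
vary between occupations, so the nominal depth is not used). Points with
non-positive total flux — possible when a negative slow flux exceeds the
fast flux — are excluded from the log fit and counted in
`n_excluded_nonpositive` so the exclusion is auditable. Whether negative
slow fluxes should instead be zeroed before summing totals is not
determinable from first principles; the default keeps them signed, and
`clamp_negative_slow = TRUE` provides the alternative for sensitivity
checks. No weighting by flux uncertainty is applied by default (a weighted
fit is available behind a flag); plain, non-robust OLS standard errors are
reported.

Two pooling rules build the profiles: one fit per station occupation
(`"by_occupation"`), or all occupations of a station pooled into a single
profile (`"by_station"`), used where individual occupations have too few
points. Profiles with fewer than three positive-flux points are emitted but
flagged unfittable.

Confidence intervals for `b` use the t quantile with the fit's residual
degrees of freedom. This matters: a typical profile has 4 depths, hence 2
residual df, where the 97.5% t quantile is 4.30 — a normal 1.96·se interval
would cover the true exponent only ~81% of the time. With the t interval
the Monte-Carlo coverage at the default study conditions is ~95%
(recomputed in the test suite and the acceptance script).

Two sensitivity analyses probe the `v_fast` assumption. The grid analysis
refits `b` for each velocity in 20/40/60/100 m d⁻¹; because the fast flux
is linear in velocity, `b` is exactly invariant when the profile is all
slow-sinking or when the fast share of total flux is depth-invariant, and
the analysis measures how far real profiles depart from those regimes. The
depth-split analysis lets velocity change with depth: profiles are split at
the arithmetic midpoint of their shallowest and deepest deployment depths
(a deployment exactly at the midpoint joins the shallow group — the
tie-break is fixed so results are deterministic), and the `"minimized"`
scheme assigns the slower velocity (40 m d⁻¹) shallow and the faster
(60 m d⁻¹) deep, inflating deep fluxes and hence lowering apparent
attenuation; `"maximized"` does the opposite.

## Projection below the deepest measurement

Fluxes below an anchor depth (typically 750 m) are extended either by
continuing the fitted power law or by an exponential
`F(z) = F_750 exp(-(z - 750)/v)` with remineralization length scale `v`.
The exponent is measured in depth *below the anchor* so the projected curve
is continuous at the anchor — an absolute-depth exponent would jump at
750 m, contradicting the idea of anchoring on the measured flux; the
absolute-depth reading remains available behind `absolute_z = TRUE` for
comparison. Projected deep BSi:POC ratios are the elementwise ratio of the
two projected flux curves after converting POC to molar units; with
`b_BSi > b_POC` the power-law ratio declines strictly with depth.
`projection_from_fit()` anchors a projection on a fitted attenuation curve
so that the projection reproduces the fit exactly over the fitted range.

## What the synthetic generator emulates — and what it does not

`synthetic_truth()` + `generate_campaign()` forward-simulate a campaign:
per-substance power-law flux profiles sampled at 4 depths (MLD+10, MLD+110,
400, 700 m with MLD = 50 m by default), a constant slow fraction of the
sinking flux, a depth-invariant suspended background, exact inversion of
the partitioning and flux equations to fraction concentrations, and
independent multiplicative lognormal noise on each measured fraction. The
noise is mean-preserving (log-scale mean −σ²/2 with σ² = log(1+cv²)), which
suits concentrations that are positive and span orders of magnitude;
additive Gaussian noise would allow negative tray concentrations at depth.
All randomness flows from one integer seed.

Defaults describe a productive Southern Ocean bloom station: POC reference
flux 200 mg m⁻² d⁻¹ with `b` = 0.4, BSi 5 mmol m⁻² d⁻¹ with `b` = 1.0
(a BSi:POC export ratio of 0.3 mol mol⁻¹ at the reference depth),
suspended background 10 µg C l⁻¹ and 0.3 µmol Si l⁻¹, a 30% slow fraction,
`v_fast` = 40 m d⁻¹ and a measurement cv of 0.2 — the magnitudes a
twilight-zone flux study in a bloom regime reports.

The generator intentionally omits features of real campaigns: lateral
advection between deployments, temporal evolution across occupations,
depth-varying true sinking velocity, correlated errors between fractions
filtered from the same catcher, and mechanistic processes (aggregation,
grazing, faecal-pellet repackaging). Passing the round-trip and recovery
tests therefore demonstrates that the inference chain is correct and
well-calibrated under the model's own assumptions — not that those
assumptions hold at sea.

## Numerical choices and degenerate inputs

* Exact power-law profiles fit with zero residual; the standard errors are
  reported as 0 and R² as 1 rather than NaN.
* Partitioning errors are explicit: a missing top/base measurement, both
  tray variants present (ambiguous), or neither (missing), each naming the
  offending deployment. Malformed table rows are collected into a rejects
  report with reasons, never silently dropped; duplicate measurement keys
  and unknown substances are hard errors.
* CSV output defaults to 6 significant digits; full precision is available
  where byte-identical round trips matter.
* Problem sizes in the tests and acceptance script: 500 replicate profiles
  for the recovery/coverage Monte Carlo, 50 random profiles for the
  grid-search cross-check (step 10⁻⁴ in `b`), 2 500 profiles for the
  mean-preservation check of the noise model. These sizes give Monte-Carlo
  error comfortably below the tolerances being asserted.

## A worked chain

```{r chain}
geom <- msc_geometry()
camp <- generate_campaign(synthetic_truth(noise_cv = 0), n_profiles = 1,
                          seed = 1)
parts <- partition_deployments(deployments_from_long(camp$concentrations),
                               geom)
fluxes <- compute_fluxes(parts, geom, v_fast = 40)
fits <- fit_attenuation(pool_profiles(fluxes, "by_station"))
fits[, c("substance", "b", "z0", "n_points")]
```

With zero noise the fitted exponents equal the generator's truth exactly
(1.0 for BSi, 0.4 for POC): the chain of partitioning, flux conversion,
pooling and log-log fitting inverts the forward model.

## Known limitations

* Bulk velocities only: no particle-size- or density-resolved velocity
  spectra; `v_fast` is a single number per record.
* The first-order uncertainty propagation ignores the shared base
  measurement between slow and fast pools.
* The attenuation fit assumes homoscedastic lognormal flux errors; strongly
  depth-dependent relative errors would call for the weighted fit.
* Deep projections are parameter extrapolations, not measurements; their
  value is in reconciling shallow fits with deep observations, and they
  inherit the full uncertainty of the fitted parameters.
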