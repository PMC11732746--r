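test_that("an exact power law is recovered with zero standard error", {
  z <- c(60, 110, 250, 500)
  f <- 200 * (z / 60)^-0.8
  fit <- fit_martin_b(z, f)
  expect_equal(fit$b, 0.8, tolerance = 1e-10)
  expect_equal(fit$b_se, 0)
  expect_equal(exp(fit$ln_f0), 200, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("the log-log OLS slope matches the hand-checked example", {
  fit <- fit_martin_b(c(60, 110, 250, 500), c(100, 60, 30, 15))
  expect_equal(fit$b, 0.889, tolerance = 1e-3)
  expect_equal(fit$z0, 60)
  expect_equal(fit$n_points, 4)
})

test_that("the fit equals an independent brute-force grid search", {
  fit <- fit_martin_b(c(60, 110, 250, 500), c(100, 60, 30, 15))
  b_grid <- grid_search_b(c(60, 110, 250, 500), c(100, 60, 30, 15))
  expect_equal(fit$b, b_grid, tolerance = 1e-3)
})

test_that("scaling all fluxes shifts the intercept, not the exponent", {
  z <- c(60, 110, 250, 500)
  f <- c(100, 60, 30, 15)
  f1 <- fit_martin_b(z, f)
  f10 <- fit_martin_b(z, 10 * f)
  expect_equal(f10$b, f1$b, tolerance = 1e-12)
  expect_equal(f10$ln_f0 - f1$ln_f0, log(10), tolerance = 1e-12)
})

test_that("non-positive fluxes are excluded and counted; too few is an error", {
  z <- c(60, 110, 250, 500, 700)
  f <- c(100, 60, 30, -2, 15)
  fit <- fit_martin_b(z, f)
  expect_equal(fit$n_excluded_nonpositive, 1)
  expect_equal(fit$n_points, 4)
  expect_error(fit_martin_b(c(60, 110, 250), c(-1, -2, -3)), "unfittable")
  expect_error(fit_martin_b(c(60, 110, 250), c(10, 5, -3)), "unfittable")
})

test_that("pooling rules group records as station or occupation profiles", {
  camp <- generate_campaign(synthetic_truth(noise_cv = 0), n_profiles = 1,
                            seed = 3)
  parts <- partition_deployments(deployments_from_long(camp$concentrations),
                                 default_geom)
  # replicate the station across three occupations
  parts3 <- do.call(rbind, lapply(c("A", "B", "C"), function(o)
    transform(parts, occupation = o,
              deployment_id = paste0(deployment_id, o))))
  fx <- compute_fluxes(parts3, default_geom, v_fast = 40)
  by_station <- pool_profiles(fx, "by_station")
  by_occ <- pool_profiles(fx, "by_occupation")
  poc_station <- by_station[by_station$substance == "POC", ]
  expect_equal(length(unique(poc_station$profile)), 1)
  expect_equal(nrow(poc_station), 12)
  poc_occ <- by_occ[by_occ$substance == "POC", ]
  expect_equal(length(unique(poc_occ$profile)), 3)
  expect_equal(as.integer(table(poc_occ$profile)), rep(4L, 3))
  # substances never share a profile
  expect_true(all(table(by_station$profile, by_station$substance) %in%
                    c(0L, 4L, 12L)))
  # every record lands in exactly one profile
  expect_equal(nrow(by_station), nrow(fx))
})

test_that("profiles with fewer than 3 positive points are flagged unfit", {
  fx <- data.frame(cruise = "C", station = "S", substance = "POC",
                   depth_m = c(60, 110, 250), f_total = c(10, -1, -2))
  pooled <- pool_profiles(fx, "by_station")
  expect_equal(attr(pooled, "unfit"), "C|S|POC")
  expect_error(fit_attenuation(pooled), "no fittable profiles")
})

test_that("b is velocity-independent when flux is all slow or fast share is flat", {
  # all slow-sinking: v_fast touches nothing
  all_slow <- generate_campaign(
    synthetic_truth(noise_cv = 0, slow_fraction = 1), seed = 2)
  parts_s <- partition_deployments(
    deployments_from_long(all_slow$concentrations), default_geom)
  sens_s <- vfast_sensitivity(parts_s, default_geom, grid = c(20, 40, 60, 100))
  for (p in unique(sens_s$profile)) {
    expect_equal(diff(range(sens_s$b[sens_s$profile == p])), 0,
                 tolerance = 1e-12)
  }
  # depth-invariant fast share: velocity rescales F(z) by a constant,
  # leaving the log-log slope alone
  flat_fast <- generate_campaign(
    synthetic_truth(noise_cv = 0, slow_fraction = 0.3), seed = 2)
  parts_f <- partition_deployments(
    deployments_from_long(flat_fast$concentrations), default_geom)
  sens_f <- vfast_sensitivity(parts_f, default_geom, grid = c(20, 40, 60, 100))
  for (p in unique(sens_f$profile)) {
    expect_equal(diff(range(sens_f$b[sens_f$profile == p])), 0,
                 tolerance = 1e-10)
  }
})

test_that("fitted exponent ordering b_BSi > b_POC holds across the grid", {
  camp <- generate_campaign(
    synthetic_truth(b_true = c(BSI = 1.0, POC = 0.4), noise_cv = 0.2),
    n_profiles = 4, seed = 9)
  parts <- partition_deployments(deployments_from_long(camp$concentrations),
                                 default_geom)
  sens <- vfast_sensitivity(parts, default_geom, grid = c(20, 40, 60, 100))
  for (v in unique(sens$v_fast)) {
    for (st in unique(sens$station)) {
      sel <- sens$v_fast == v & sens$station == st
      expect_gt(sens$b[sel & sens$substance == "BSI"],
                sens$b[sel & sens$substance == "POC"])
    }
  }
})

test_that("depth-split schemes collapse to the uniform fit without fast flux", {
  camp <- generate_campaign(synthetic_truth(noise_cv = 0, slow_fraction = 1),
                            seed = 4)
  parts <- partition_deployments(deployments_from_long(camp$concentrations),
                                 default_geom)
  uni <- fit_attenuation(pool_profiles(
    compute_fluxes(parts, default_geom, v_fast = 40), "by_station"))
  mini <- depth_split_b(parts, default_geom, "minimized")
  maxi <- depth_split_b(parts, default_geom, "maximized")
  expect_equal(mini$b, uni$b, tolerance = 1e-12)
  expect_equal(maxi$b, uni$b, tolerance = 1e-12)
})

test_that("depth-split schemes shift b symmetrically around the uniform fit", {
  camp <- generate_campaign(synthetic_truth(noise_cv = 0), seed = 4)
  parts <- partition_deployments(deployments_from_long(camp$concentrations),
                                 default_geom)
  uni40 <- fit_attenuation(pool_profiles(
    compute_fluxes(parts, default_geom, v_fast = 40), "by_station"))
  mini <- depth_split_b(parts, default_geom, "minimized")
  maxi <- depth_split_b(parts, default_geom, "maximized")
  key <- c("station", "substance")
  m <- Reduce(function(a, b) merge(a, b, by = key),
              list(uni40[c(key, "b")],
                   setNames(mini[c(key, "b")], c(key, "b_min")),
                   setNames(maxi[c(key, "b")], c(key, "b_max"))))
  # faster velocity at depth inflates deep fluxes -> lower apparent b
  expect_true(all(m$b_min < m$b))
  expect_true(all(m$b_max > m$b))
  # swapping the symmetric velocity pair inverts the direction of the shift
  expect_true(all(sign(m$b_min - m$b) == -sign(m$b_max - m$b)))
  expect_identical(unique(mini$scheme), "minimized")
  expect_identical(unique(maxi$scheme), "maximized")
})

test_that("fits are deterministic given the same input table", {
  camp <- generate_campaign(synthetic_truth(), n_profiles = 2, seed = 8)
  parts <- partition_deployments(deployments_from_long(camp$concentrations),
                                 default_geom)
  pooled <- pool_profiles(compute_fluxes(parts, default_geom, v_fast = 40),
                          "by_station")
  expect_identical(fit_attenuation(pooled), fit_attenuation(pooled))
})

test_that("weighted fits accept per-point flux uncertainties", {
  z <- c(60, 110, 250, 500)
  f <- c(100, 60, 30, 15)
  fit_w <- fit_martin_b(z, f, sd_f_total = 0.1 * f, weighted = TRUE)
  fit_u <- fit_martin_b(z, f)
  # constant relative error: weights are uniform, so both fits agree
  expect_equal(fit_w$b, fit_u$b, tolerance = 1e-10)
  expect_error(fit_martin_b(z, f, weighted = TRUE), "needs sd_f_total")
})
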