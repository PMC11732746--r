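test_that("suspended pool is the top fraction unchanged", {
  expect_identical(suspended_concentration(1.0), 1.0)
  expect_identical(suspended_concentration(0.0), 0.0)
  expect_identical(suspended_concentration(3.7), 3.7) # BSi, umol l-1 passthrough
  expect_error(suspended_concentration(NA_real_, "D1"),
               "missing measurement p_top.*D1")
})

test_that("slow pool is the signed base-top difference rescaled by volumes", {
  expect_equal(slow_concentration(1.0, 2.0, default_geom), 8 / 95,
               tolerance = 1e-12)
  expect_equal(slow_concentration(5.0, 5.0, default_geom), 0)
  # negative value preserved: upward flux of material, not clamped
  expect_equal(slow_concentration(2.0, 1.5, default_geom), -0.5 * 8 / 95,
               tolerance = 1e-12)
  expect_error(slow_concentration(NA_real_, 1, default_geom),
               "missing measurement")
})

test_that("slow pool is antisymmetric under top/base exchange", {
  set.seed(7)
  a <- runif(20, 0, 10)
  b <- runif(20, 0, 10)
  expect_equal(slow_concentration(a, b, default_geom),
               -slow_concentration(b, a, default_geom))
})

test_that("fast pool uses the tray variant and records the method", {
  pf <- fast_concentration(2.0, p_tray = 10.0, geom = default_geom)
  expect_equal(as.numeric(pf), 8 / (0.026 * 1.58 * 1000), tolerance = 1e-12)
  expect_equal(as.numeric(pf), 0.19474, tolerance = 1e-4)
  expect_identical(attr(pf, "method"), "tray")
  expect_equal(as.numeric(fast_concentration(3.0, p_tray = 3.0,
                                             geom = default_geom)), 0)
})

test_that("fast pool uses the syphoned-tray variant when supplied", {
  pf <- fast_concentration(2.0, p_tray_star = 3.0, v_tray_star_l = 9.5,
                           geom = default_geom)
  expect_equal(as.numeric(pf), 1.0 * 9.5 / 95, tolerance = 1e-12)
  expect_identical(attr(pf, "method"), "tray_star")
})

test_that("exactly one fast-measurement variant must be present", {
  expect_error(
    fast_concentration(2, p_tray = 10, p_tray_star = 3, v_tray_star_l = 9.5,
                       geom = default_geom, deployment_id = "D9"),
    "ambiguous.*D9")
  expect_error(fast_concentration(2, geom = default_geom),
               "missing fast-sinking measurement")
  expect_error(fast_concentration(2, p_tray_star = 3, geom = default_geom),
               "v_tray_star_l")
})

test_that("the decomposition is linear in the measured concentrations", {
  set.seed(11)
  for (c_scale in runif(5, 0.1, 10)) {
    top <- 1.3; base <- 2.9; tray <- 14.2
    expect_equal(slow_concentration(c_scale * top, c_scale * base,
                                    default_geom),
                 c_scale * slow_concentration(top, base, default_geom))
    expect_equal(
      as.numeric(fast_concentration(c_scale * base, c_scale * tray,
                                    geom = default_geom)),
      c_scale * as.numeric(fast_concentration(base, tray,
                                              geom = default_geom)))
  }
})

test_that("partitioning a table propagates sd and records one method per row", {
  camp <- noise_free_campaign()
  wide <- deployments_from_long(camp$concentrations)
  # mix in one syphoned-tray deployment
  wide$p_tray_star <- NA_real_
  wide$p_tray_star[1] <- wide$p_tray[1]
  wide$v_tray_star_l[1] <- 9.5
  wide$p_tray[1] <- NA_real_
  parts <- partition_deployments(wide, default_geom)
  expect_true(all(parts$method_fast %in% c("tray", "tray_star")))
  expect_identical(parts$method_fast[1], "tray_star")
  expect_identical(parts$p_susp, parts$p_top)
})

test_that("first-order sd propagation follows the quadrature rule", {
  wide <- data.frame(
    cruise = "DY111", station = "X", occupation = "O1",
    deployment_id = "D1", depth_m = 100, substance = "POC",
    p_top = 1.0, p_base = 2.0, p_tray = 10.0,
    sd_top = 0.3, sd_base = 0.4, sd_tray = 0.5
  )
  parts <- partition_deployments(wide, default_geom)
  expect_equal(parts$sd_slow, 0.5 * 8 / 95, tolerance = 1e-12) # sqrt(.09+.16)
  expect_equal(parts$sd_fast,
               sqrt(0.5^2 + 0.4^2) / (0.026 * 1.58 * 1000),
               tolerance = 1e-12)
  # no sd supplied -> NA, never fabricated
  wide2 <- wide[setdiff(names(wide), c("sd_top", "sd_base", "sd_tray"))]
  parts2 <- partition_deployments(wide2, default_geom)
  expect_true(is.na(parts2$sd_slow) && is.na(parts2$sd_fast))
})
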