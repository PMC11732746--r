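test_that("POC mass-to-mol conversion uses the molar mass of carbon", {
  expect_equal(poc_mass_to_mol(12.011), 1.0)
  expect_equal(poc_mass_to_mol(0), 0)
  expect_equal(poc_mass_to_mol(60.055), 5.0)
})

test_that("total-sinking ratio sums pools before dividing", {
  expect_equal(total_sinking_ratio(0.5, 0.5, 12.011, 12.011), 0.5)
  # all pools positive: plain (slow+fast)/(slow+fast) in moles
  expect_equal(total_sinking_ratio(0.3, 0.7, 24.022, 0),
               (0.3 + 0.7) / 2)
})

test_that("negative slow pools enter by magnitude, not subtraction", {
  # |-0.2| + 0.8 = 1.0 in the numerator
  expect_equal(total_sinking_ratio(-0.2, 0.8, 0, 12.011), 1.0)
  # same rule on the POC denominator
  expect_equal(total_sinking_ratio(0, 1, -12.011, 12.011), 0.5)
  # the drop rule contributes zero instead
  expect_equal(total_sinking_ratio(-0.2, 0.8, 0, 12.011,
                                   negative_rule = "drop"), 0.8)
})

test_that("ratios are invariant under common rescaling of concentrations", {
  r1 <- total_sinking_ratio(0.5, 0.5, 12.011, 12.011)
  r10 <- total_sinking_ratio(5, 5, 120.11, 120.11)
  expect_equal(r1, r10)
})

test_that("non-positive denominators are flagged, not dropped", {
  expect_warning(r <- total_sinking_ratio(0.5, 0.5, 0, 0), "non-positive")
  expect_true(is.nan(r))
})

test_that("per-deployment ratios cover all fractions of a fixture", {
  fx <- generate_ratio_profile_fixture()
  parts <- partition_deployments(deployments_from_long(fx$concentrations),
                                 default_geom)
  recs <- molar_ratios(parts)
  expect_setequal(unique(recs$fraction),
                  c("time_zero", "suspended", "slow", "fast",
                    "total_sinking"))
  # noise-free fixture: total-sinking ratio equals the truth's flux ratio
  tr <- fx$truth
  true_ratio <- tr$f_total_true[tr$substance == "BSI"] /
    poc_mass_to_mol(tr$f_total_true[tr$substance == "POC"])
  got <- recs[recs$fraction == "total_sinking", ]
  got <- got[order(got$depth_m), ]
  expect_equal(got$ratio, true_ratio, tolerance = 1e-10)
})

test_that("aggregation reports mean, sample sd and group size", {
  recs <- data.frame(station = "P3", occupation = "A", depth_m = 500,
                     fraction = "total_sinking", ratio = c(0.2, 0.4))
  agg <- aggregate_ratios(recs)
  expect_equal(agg$ratio, 0.3)
  expect_equal(agg$sd, sd(c(0.2, 0.4)), tolerance = 1e-6)
  expect_equal(agg$sd, 0.1414, tolerance = 1e-3)
  expect_equal(agg$n_deployments, 2)
  # single deployment: sd undefined, not zero
  agg1 <- aggregate_ratios(recs[1, ])
  expect_equal(agg1$ratio, 0.2)
  expect_true(is.na(agg1$sd))
  # order invariance
  agg_rev <- aggregate_ratios(recs[2:1, ])
  expect_equal(agg, agg_rev)
})

test_that("depth trend in total-sinking ratios survives the negative rule", {
  # small negative slow pools at every depth; the sign of the ratio-depth
  # trend must not depend on how negatives are handled
  fx <- generate_ratio_profile_fixture(negative_slow = 0.01)
  parts <- partition_deployments(deployments_from_long(fx$concentrations),
                                 default_geom)
  expect_true(any(parts$p_slow < 0))
  trend <- function(rule) {
    recs <- molar_ratios(parts, fractions = "total_sinking",
                         negative_rule = rule)
    cor(recs$ratio, recs$depth_m, method = "spearman")
  }
  expect_identical(sign(trend("magnitude")), sign(trend("drop")))
  expect_lt(trend("magnitude"), 0) # b_BSi > b_POC: ratio falls with depth
})
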