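test_that("cohort generation is deterministic and nonnegative", {
  spec <- cohort_spec(10, 0, 10, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_length(a$spectra, 20)
  expect_true(all(vapply(a$spectra, function(s) all(s$intensities >= 0), logical(1))))
  expect_equal(as.integer(group_counts(a$metadata)), c(10L, 0L, 10L))
  expect_error(cohort_spec(0, 0, 0), "empty cohort")
})

test_that("default effects reproduce the reported zone orderings", {
  sc <- make_small_cohort(50, 0, 50, seed = 21)
  zt <- sc$zones
  mn <- function(v, g) mean(zt[[v]][zt$group == g])
  expect_gt(mn("Z1a", "control"), mn("Z1a", "malignant"))
  expect_gt(mn("Z1b", "control"), mn("Z1b", "malignant"))
  expect_gt(mn("Z3", "malignant"), mn("Z3", "control"))
  expect_gt(mn("Z6", "control"), mn("Z6", "malignant"))
  expect_gt(mn("Z7", "malignant"), mn("Z7", "control"))
  # structural: the 3-HAA band is switched off outside the malignant group
  eff <- group_effect_profile()
  expect_equal(unname(eff$multipliers[c("control", "benign"), "haa_3"]), c(0, 0))
  expect_gt(eff$multipliers["malignant", "haa_3"], 0)
  # malignant red shift of the NADH-like band
  expect_equal(unname(eff$center_shift_nm["malignant", "nadh_like"]), 6)
})

test_that("dilution series follows the quench model", {
  sp <- make_profile(data.frame(center = 350, width = 15, amp = 400))
  sp <- syn_spectrum("S1", sp$intensities, sp$grid)
  # no quench: exact 1/f scaling
  ser0 <- generate_dilution_series(sp, factors = c(1, 3, 9), quench_strength = 0)
  expect_equal(ser0[[2]]$intensities, sp$intensities / 3, tolerance = 1e-12)
  expect_equal(ser0[[3]]$intensities, sp$intensities / 9, tolerance = 1e-12)
  # the study's geometric series gives seven spectra
  ser <- generate_dilution_series(sp, factors = 3^(0:6), quench_strength = 3)
  expect_length(ser, 7)
  expect_equal(vapply(ser, function(s) s$dilution_factor, numeric(1)), 3^(0:6))
  # with quench q > 1 the per-wavelength maximum is attained at an interior
  # factor; on a dense grid that factor equals q (oracle: evaluate the
  # quench curve c * exp(q * (1 - c)) over the factor grid)
  dense <- seq(1, 20, by = 0.25)
  serq <- generate_dilution_series(sp, factors = dense, quench_strength = 5)
  peak <- sapply(serq, function(s) s$intensities[200])
  curve <- (1 / dense) * exp(5 * (1 - 1 / dense))
  expect_equal(which.max(peak), which.max(curve))
  expect_equal(dense[which.max(peak)], 5)
  expect_error(generate_dilution_series(sp, factors = c(0.5, 1)), ">= 1")
})

test_that("strip covariates match the configured positivity rates and pH", {
  big <- generate_strip_covariates("control", 6000, seed = 3)
  expect_equal(mean(big$leukocytes), 4 / 96, tolerance = 0.3)
  expect_equal(mean(big$pH), 6.06, tolerance = 0.02)
  bigm <- generate_strip_covariates("malignant", 6000, seed = 4)
  expect_equal(mean(bigm$leukocytes), 61 / 77, tolerance = 0.02)
  expect_equal(mean(bigm$pH), 5.69, tolerance = 0.02)
  bigb <- generate_strip_covariates("benign", 6000, seed = 5)
  expect_equal(mean(bigb$pH), 6.43, tolerance = 0.02)
  expect_true(all(big$pH >= 4.5 & big$pH <= 9))
  expect_error(generate_strip_covariates("cancer", 5), "unknown group")
})

test_that("null effect profile makes groups exchangeable in zone features", {
  sc <- make_small_cohort(40, 0, 40, seed = 13, effect = null_effect_profile())
  zt <- sc$zones
  sub <- zt[zt$group != "benign", ]
  auc <- roc_analysis(sub$Z6_over_Z7, as.character(sub$group),
                      polarity = "lower_is_positive",
                      positive = "malignant")$auc
  expect_lt(abs(auc - 0.5), 0.18)   # single small cohort, loose bound
  p <- test_group_differences(zt, "Z1a")$global_p
  expect_gt(p, 0.001)
})
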