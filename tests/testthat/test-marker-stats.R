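test_that("Wilson interval matches the closed form and prop.test", {
  z <- 1.959964
  for (case in list(c(0, 10), c(5, 10), c(19, 20), c(50, 100), c(1, 7))) {
    s <- case[1]; n <- case[2]
    ci <- wilson_interval(s, n)
    p <- s / n
    center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    expect_equal(ci$lower, max(center - half, 0), tolerance = 1e-7)
    expect_equal(ci$upper, min(center + half, 1), tolerance = 1e-7)
    # independent oracle: prop.test without continuity correction inverts
    # the same score test
    pt <- suppressWarnings(prop.test(s, n, correct = FALSE))
    expect_equal(ci$lower, pt$conf.int[1], tolerance = 1e-6)
    expect_equal(ci$upper, pt$conf.int[2], tolerance = 1e-6)
  }
  expect_equal(wilson_interval(0, 10)$lower, 0)
  expect_error(wilson_interval(11, 10), "successes")
  # large n: converges to the Wald interval
  n <- 1e5; s <- 0.37 * n
  ci <- wilson_interval(s, n)
  wald <- 0.37 + c(-1, 1) * 1.959964 * sqrt(0.37 * 0.63 / n)
  expect_equal(c(ci$lower, ci$upper), wald, tolerance = 1e-3)
})

test_that("Dunn post hoc matches a hand-computed tie-free example", {
  # groups of 3/3/3 with fully distinct values: mean ranks 2, 5, 8
  x <- c(1, 2, 3, 11, 12, 13, 21, 22, 23)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  dn <- dunn_test(x, g)
  s2 <- 9 * 10 / 12                       # N(N+1)/12, no ties
  z_ab <- (2 - 5) / sqrt(s2 * (2 / 3))
  expect_equal(dn$z[dn$pair == "a vs b"], z_ab, tolerance = 1e-12)
  expect_equal(dn$p_raw[1], 2 * pnorm(-abs(z_ab)), tolerance = 1e-12)
  expect_true(all(dn$p_adj >= dn$p_raw))
  expect_true(all(dn$p_adj <= 1))
  expect_equal(dn$p_adj, pmin(3 * dn$p_raw, 1), tolerance = 1e-12)
})

test_that("group testing gates on normality and handles degenerate input", {
  sc <- make_small_cohort(15, 8, 15, seed = 31)
  res <- test_group_differences(sc$zones, "Z6_over_Z7")
  expect_true(res$test %in% c("kruskal_wallis", "anova"))
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= 0 & res$pairwise$p_adj <= 1))
  expect_equal(res$summary$group, c("control", "benign", "malignant"))
  # forced branches
  expect_equal(test_group_differences(sc$zones, "Z1a", mode = "nonparametric")$test,
               "kruskal_wallis")
  expect_equal(test_group_differences(sc$zones, "Z1a", mode = "parametric")$test,
               "anova")
  # identical values everywhere: degenerate, p = 1 on all comparisons
  tab <- data.frame(group = rep(c("control", "benign", "malignant"), each = 5),
                    v = 3)
  dres <- test_group_differences(tab, "v")
  expect_equal(dres$global_p, 1)
  expect_true(all(dres$pairwise$p_adj == 1))
  # insufficient data
  tab2 <- data.frame(group = rep(c("control", "malignant"), c(10, 2)), v = rnorm(12))
  expect_error(test_group_differences(tab2, "v"), "insufficient")
})

test_that("global nonparametric test holds its type-I error rate", {
  withr::with_seed(77, {
    rejections <- vapply(1:1000, function(i) {
      tab <- data.frame(group = rep(c("control", "benign", "malignant"), each = 10),
                        v = rnorm(30))
      test_group_differences(tab, "v", mode = "nonparametric")$global_p < 0.05
    }, logical(1))
  })
  expect_equal(mean(rejections), 0.05, tolerance = 0.4)  # ~5% +/- MC error
})

test_that("ROC analysis behaves at the boundaries and agrees with pROC", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, 1.0)
  expect_true(all(r$sweep$sensitivity >= r$sweep$sens_lower - 1e-12 &
                  r$sweep$sensitivity <= r$sweep$sens_upper + 1e-12))
  # polarity flip is exact for tie-free scores
  r_lo <- roc_analysis(-scores, labels, polarity = "lower_is_positive")
  expect_equal(r_lo$auc, 1.0)
  withr::with_seed(5, {
    s <- rnorm(60); lab <- rep(c(TRUE, FALSE), 30)
  })
  mine <- roc_analysis(s, lab)
  ref <- suppressMessages(pROC::auc(pROC::roc(response = lab, predictor = s,
                                              direction = "<", quiet = TRUE)))
  expect_equal(mine$auc, as.numeric(ref), tolerance = 1e-12)
  expect_equal(mine$auc + roc_analysis(-s, lab)$auc, 1, tolerance = 1e-12)
  # monotone transform invariance
  expect_equal(roc_analysis(exp(s), lab)$auc, mine$auc, tolerance = 1e-12)
  expect_error(roc_analysis(s, rep(TRUE, 60)), "both classes")
  expect_error(roc_analysis(c(NA, s[-1]), lab), "missing")
})

test_that("Hanley-McNeil AUC uncertainty is coherent", {
  withr::with_seed(9, {
    s <- c(rnorm(100), rnorm(100, 1))
    lab <- rep(c(FALSE, TRUE), each = 100)
  })
  r <- roc_analysis(s, lab)
  expect_gt(r$auc_se, 0)
  expect_true(r$auc_ci_95[1] <= r$auc && r$auc <= r$auc_ci_95[2])
  expect_lt(r$p_value, 0.01)   # a real effect at n = 100/100
})
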