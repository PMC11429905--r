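test_that("stratified split preserves class proportions and is seeded", {
  tab <- data.frame(
    sample_id = sprintf("S%03d", 1:173),
    group = factor(rep(c("control", "malignant"), c(96, 77)),
                   levels = c("control", "benign", "malignant")),
    f1 = rnorm(173))
  sp <- stratified_split(tab, 0.3, seed = 4)
  expect_equal(nrow(sp$test), round(96 * 0.3) + round(77 * 0.3))
  expect_equal(sum(sp$test$group == "control"), round(96 * 0.3))
  expect_equal(sum(sp$test$group == "malignant"), round(77 * 0.3))
  expect_equal(sort(c(sp$train$sample_id, sp$test$sample_id)), tab$sample_id)
  # proportions within 2 percentage points of 96:77
  expect_lt(abs(mean(sp$test$group == "control") - 96 / 173), 0.02)
  sp2 <- stratified_split(tab, 0.3, seed = 4)
  expect_identical(sp, sp2)
  tiny <- tab[c(1:3, 97:99), ]
  tiny$group <- droplevels(tiny$group)
  expect_silent(stratified_split(tiny, 0.3, seed = 1))
  expect_error(stratified_split(tab[c(1, 97:100), ], 0.3), "stratification")
})

test_that("stratified folds deviate by at most one sample per class", {
  y <- factor(rep(c("control", "malignant"), c(67, 54)))
  folds <- stratified_folds(y, k = 10, seed = 2)
  expect_equal(sort(unique(folds)), 1:10)
  per_class <- table(folds, y)
  for (cl in colnames(per_class))
    expect_lte(diff(range(per_class[, cl])), 1)
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(5, 50))), 10),
               "stratification")
})

test_that("metric panel matches hand formulas, with guarded ratios", {
  m <- suppressMessages(metrics_from_confusion(16, 2, 18, 4))
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.9)
  expect_equal(unname(m["plr"]), 8.0)
  expect_equal(unname(m["nlr"]), 0.2 / 0.9)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["ppv"]), 16 / 18)
  expect_equal(unname(m["npv"]), 18 / 22)
  mz <- suppressMessages(metrics_from_confusion(10, 0, 20, 5))
  expect_equal(unname(mz["specificity"]), 1.0)
  expect_true(is.na(mz["plr"]))
  expect_error(metrics_from_confusion(-1, 0, 1, 1), "negative")
  # formula oracle on random confusion matrices
  withr::with_seed(12, {
    for (i in 1:1000) {
      cts <- rpois(4, 10) + c(1, 0, 1, 0)
      m <- suppressMessages(metrics_from_confusion(cts[1], cts[2], cts[3], cts[4]))
      sens <- cts[1] / (cts[1] + cts[4]); spec <- cts[3] / (cts[3] + cts[2])
      expect_equal(unname(m["sensitivity"]), sens)
      expect_equal(unname(m["specificity"]), spec)
      expect_equal(unname(m["accuracy"]), (cts[1] + cts[3]) / sum(cts))
      if (spec < 1) expect_equal(unname(m["plr"]), sens / (1 - spec))
      if (spec > 0) expect_equal(unname(m["nlr"]), (1 - sens) / spec)
    }
  })
})

test_that("all four models separate well-separated clusters", {
  tab <- make_separated_table(n_per_class = 50, gap = 6, p = 2, seed = 3)
  rep <- suppressMessages(run_suite(tab, n_folds = 5, n_reps = 1, seed = 10))
  expect_true(all(rep$cv_summary$auc >= 0.95))
  expect_true(all(rep$test$accuracy >= 0.9))
  expect_equal(nrow(rep$cv_summary), 4)
})

test_that("the suite is deterministic and internally consistent", {
  sc <- make_small_cohort(20, 0, 20, seed = 15)
  tabs <- list(zones = sc$zones)
  r1 <- suppressMessages(run_suite(tabs, n_folds = 5, n_reps = 2, seed = 99))
  r2 <- suppressMessages(run_suite(tabs, n_folds = 5, n_reps = 2, seed = 99))
  expect_identical(r1$cv, r2$cv)
  expect_identical(r1$test, r2$test)
  # per-fold confusion cells sum to the fold size; metric identities hold
  n_train <- 40 - round(20 * 0.3) * 2
  per_class <- n_train / 2
  fold_sizes <- r1$cv$tp + r1$cv$fp + r1$cv$tn + r1$cv$fn
  # each class contributes floor or ceiling of per_class/k to every fold
  expect_true(all(fold_sizes >= 2 * floor(per_class / 5) &
                  fold_sizes <= 2 * ceiling(per_class / 5)))
  ok <- with(r1$cv, {
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    all(abs(sensitivity - sens) < 1e-12, na.rm = TRUE) &&
      all(abs(accuracy - (tp + tn) / fold_sizes) < 1e-12) &&
      all(abs(plr - sens / (1 - spec))[is.finite(plr) & spec < 1] < 1e-9, na.rm = TRUE)
  })
  expect_true(ok)
  # pooled confusion sums every validation prediction
  total <- sum(vapply(r1$pooled_confusion, sum, numeric(1)))
  expect_equal(total, n_train * 2 * 4)       # folds x reps x models
  expect_error(run_suite(tabs, models = list(model_spec("RF"), model_spec("RF"))),
               "duplicate")
})

test_that("PLS-DA fits, reports the study panel, and rejects degenerate input", {
  tab <- make_separated_table(n_per_class = 60, gap = 6, p = 4, seed = 6)
  sp <- stratified_split(tab, 0.3, seed = 2)
  fit <- fit_plsda(sp$train, sp$test, n_components = 2, seed = 5)
  expect_gte(fit$accuracy, 0.98)
  expect_gte(fit$auc, 0.99)
  expect_gt(fit$r2, 0.8)
  expect_lte(fit$q2, fit$r2 + 0.05)
  expect_equal(sum(fit$report$support), nrow(sp$test))
  expect_equal(fit$report$class, c("control", "malignant"))
  expect_equal(dim(fit$scores), c(nrow(sp$train), 2L))
  const <- sp$train; const$group <- factor("control", levels = levels(const$group))
  expect_error(fit_plsda(const, sp$test), "degenerate")
  expect_error(fit_plsda(sp$train, sp$test, n_components = 1000), "dimension")
})

test_that("permuted labels destroy PLS-DA predictive power", {
  sc <- make_small_cohort(25, 0, 25, seed = 19)
  X <- as.matrix(sc$zones[, !(names(sc$zones) %in% c("sample_id", "group"))])
  y <- as.numeric(sc$zones$group == "malignant")
  q2s <- withr::with_seed(4, {
    vapply(1:25, function(i) utfmp:::plsda_q2(X, sample(y), 2, k = 5, seed = i),
           numeric(1))
  })
  expect_lte(mean(q2s), 0.05)
})
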