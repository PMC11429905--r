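#' Model specification for the classifier suite
#'
#' Hyperparameters default to the configurations selected in the study's
#' tuning grids: random forest with 150 trees of maximum depth 10 (grids
#' 100/150/200 trees, depth 5/10/15), RBF support vector machine with
#' C = 1 (grid 0.01/0.1/1), L2 logistic regression with C = 1 and an
#' iteration cap of 1000, and stochastic gradient descent with logistic
#' loss, alpha = 1e-4 (grid 1e-6/1e-4/1e-2) and the "optimal" decaying
#' learning-rate schedule.
#'
#' @param model One of `"RF"`, `"SVM"`, `"LR"`, `"SGD"`.
#' @param ... Hyperparameter overrides (see Details above for names:
#'   RF `trees`, `max_depth`; SVM `cost`; LR `C`, `maxit`; SGD `alpha`,
#'   `epochs`).
#' @export
model_spec <- function(model = c("RF", "SVM", "LR", "SGD"), ...) {
  model <- match.arg(model)
  defaults <- switch(model,
    RF = list(trees = 150, max_depth = 10),
    SVM = list(cost = 1),
    LR = list(C = 1, maxit = 1000),
    SGD = list(alpha = 1e-4, epochs = 100, schedule = "optimal"))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop(sprintf("model_spec: unknown hyperparameter '%s' for %s", unknown[1], model))
  defaults[names(over)] <- over
  structure(list(model = model, params = defaults), class = "model_spec")
}

#' Default suite: all four models at study hyperparameters
#' @export
default_models <- function() {
  lapply(c("RF", "SVM", "LR", "SGD"), model_spec)
}

#' Stratified train/test split
#'
#' Per-class random partition at the study's 70:30 ratio: each class
#' contributes `round(n_class * test_fraction)` samples to the test set,
#' so class proportions are preserved up to rounding. Deterministic per
#' seed.
#'
#' @param table Feature table with a `group` column (>= 2 samples/class).
#' @param test_fraction Held-out fraction (default 0.3).
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables.
#' @export
stratified_split <- function(table, test_fraction = 0.3, seed = 1) {
  g <- droplevels(as.factor(table$group))
  n_g <- table(g)
  if (any(n_g < 2))
    stop(sprintf("stratified_split: stratification error - class '%s' has %d < 2 samples",
                 names(n_g)[which.min(n_g)], min(n_g)))
  test_idx <- with_seed(seed, {
    unlist(lapply(levels(g), function(lv) {
      idx <- which(g == lv)
      sample(idx, round(length(idx) * test_fraction))
    }))
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds so that every fold's class
#' proportions deviate from the parent's by at most one sample per class:
#' samples are shuffled within class and dealt round-robin.
#'
#' @param labels Factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per sample.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  g <- droplevels(as.factor(labels))
  if (any(table(g) < k))
    stop(sprintf("stratified_folds: stratification error - a class has fewer than %d samples", k))
  fold <- integer(length(g))
  with_seed(seed, {
    for (lv in levels(g)) {
      idx <- sample(which(g == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Standardize columns by training statistics; zero-variance columns are
# centred only (leakage-free scaling, fitted per training fold).
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# --- model backends ---------------------------------------------------------
# All backends take a standardized numeric matrix X, a 0/1 response y
# (1 = positive class) and a seed, and return continuous scores in [0, 1]
# for new data; the predicted class is score >= 0.5 (SVM uses its own
# class prediction and signed decision values rescaled through a logistic
# link for ranking).

fit_model <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  p <- spec$params
  yf <- factor(y, levels = c(0, 1))
  obj <- switch(spec$model,
    RF = ranger::ranger(
      x = X, y = yf, num.trees = p$trees, max.depth = p$max_depth,
      probability = TRUE, seed = seed, num.threads = 1),
    SVM = e1071::svm(
      x = X, y = yf, kernel = "radial", cost = p$cost, scale = FALSE),
    LR = {
      # ridge-penalised logistic regression at lambda = 1/(C*n); glmnet is
      # fit along a short decreasing path for numerical stability and
      # evaluated at the target lambda
      lam <- 1 / (p$C * nrow(X))
      list(fit = glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                                lambda = lam * c(100, 25, 5, 1),
                                maxit = p$maxit, standardize = FALSE),
           s = lam)
    },
    SGD = fit_sgd_logistic(X, y, alpha = p$alpha, epochs = p$epochs, seed = seed))
  structure(list(model = spec$model, fit = obj), class = "utfmp_model")
}

predict_scores <- function(fit, X) {
  switch(fit$model,
    RF = ranger::predictions(predict(fit$fit, data = X, num.threads = 1))[, "1"],
    SVM = {
      dv <- attr(predict(fit$fit, X, decision.values = TRUE), "decision.values")
      # orient decision values so larger means class "1"
      sgn <- if (grepl("^0/1$", colnames(dv)[1])) -1 else 1
      plogis(sgn * dv[, 1])
    },
    LR = as.numeric(predict(fit$fit$fit, X, type = "response", s = fit$fit$s)),
    SGD = as.numeric(plogis(X %*% fit$fit$w + fit$fit$b)))
}

# Stochastic gradient descent for L2-regularised logistic loss with the
# scikit-learn style "optimal" schedule eta_t = 1 / (alpha * (t + t0)),
# t0 = 1 / (eta0 * alpha) from the typical-weight heuristic. Per-sample
# updates, reshuffled every epoch.
fit_sgd_logistic <- function(X, y, alpha = 1e-4, epochs = 100, seed = 1) {
  n <- nrow(X); d <- ncol(X)
  ypm <- ifelse(y == 1, 1, -1)
  typw <- sqrt(1 / sqrt(alpha))
  eta0 <- typw / max(1, 1 / (1 + exp(-typw)))
  t0 <- 1 / (eta0 * alpha)
  w <- numeric(d); b <- 0; t <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (alpha * (t + t0))
        z <- sum(X[i, ] * w) + b
        gz <- -ypm[i] / (1 + exp(ypm[i] * z))
        w <- w * (1 - eta * alpha) - eta * gz * X[i, ]
        b <- b - eta * gz
      }
    }
  })
  list(w = w, b = b)
}

#' Performance panel from a confusion matrix
#'
#' Sensitivity, specificity, PPV, NPV, positive and negative likelihood
#' ratios, accuracy, and (when scores and labels are supplied) the AUC.
#' Ratios with a zero denominator are reported as `NA` with a logged
#' reason, never as 0.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts (total > 0).
#' @param scores,labels Optional continuous scores and logical positive
#'   labels for the AUC.
#' @return Named numeric vector: sensitivity, specificity, ppv, npv, plr,
#'   nlr, accuracy, auc.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn, scores = NULL, labels = NULL) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("metrics_from_confusion: negative counts")
  if (sum(counts) == 0) stop("metrics_from_confusion: empty confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) {
      utfmp_log("classifiers", sprintf("%s undefined (zero denominator)", what))
      NA_real_
    } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  out <- c(
    sensitivity = sens,
    specificity = spec,
    ppv = safe(tp, tp + fp, "PPV"),
    npv = safe(tn, tn + fn, "NPV"),
    plr = if (!is.na(spec) && spec == 1) {
      utfmp_log("classifiers", "PLR undefined (specificity = 1)")
      NA_real_
    } else safe(sens, 1 - spec, "PLR"),
    nlr = if (!is.na(spec) && spec == 0) {
      utfmp_log("classifiers", "NLR undefined (specificity = 0)")
      NA_real_
    } else safe(1 - sens, spec, "NLR"),
    accuracy = (tp + tn) / sum(counts),
    auc = if (!is.null(scores) && !is.null(labels) &&
              length(unique(labels)) == 2)
      roc_analysis(scores, labels)$auc else NA_real_)
  out
}

#' Repeated stratified cross-validation suite
#'
#' The study's four-classifier evaluation on control-vs-malignant feature
#' tables. For each representation the data are split 70:30 (stratified),
#' repeated stratified k-fold cross-validation is run on the training
#' partition (per-fold leakage-free standardization; repetition `r`
#' shuffles folds with seed `base + r`), and each model is finally refit
#' on the full training partition and evaluated on the held-out test set.
#' Benign samples are excluded.
#'
#' @param tables One feature table or a named list of tables, one per
#'   representation (e.g. `list(zones = ..., utfmp = ...)`).
#' @param models List of [model_spec()] objects.
#' @param n_folds,n_reps Cross-validation protocol (study: 10 folds, 100
#'   repetitions; the desk profile uses 10 repetitions).
#' @param test_fraction Held-out fraction of the initial split.
#' @param seed Base seed; all randomness derives from it.
#' @return Object of class `cv_report`: list with `cv` (per
#'   representation/model/repetition/fold metric rows), `cv_summary`
#'   (mean/sd over folds and repetitions), `pooled_confusion` (summed CV
#'   validation predictions), `pooled_metrics` (panel recomputed from the
#'   pooled counts), `test` (held-out panel per model), `test_roc`
#'   (ROC curves on the held-out partition).
#' @export
run_suite <- function(tables, models = default_models(), n_folds = 10,
                      n_reps = 10, test_fraction = 0.3, seed = 1) {
  if (is.data.frame(tables)) {
    rep_name <- attr(tables, "representation")
    tables <- setNames(list(tables), if (is.null(rep_name)) "features" else rep_name)
  }
  model_names <- vapply(models, function(m) m$model, character(1))
  if (anyDuplicated(model_names)) stop("run_suite: duplicate models")
  cv_rows <- list(); test_rows <- list()
  pooled <- list(); rocs <- list()
  for (rep_name in names(tables)) {
    tab <- tables[[rep_name]]
    tab <- tab[tab$group %in% c("control", "malignant"), , drop = FALSE]
    tab$group <- droplevels(tab$group)
    if (nlevels(tab$group) != 2)
      stop("run_suite: need both control and malignant samples")
    split <- stratified_split(tab, test_fraction, seed = derive_seed(seed, 0L))
    Xtr_all <- feature_matrix(split$train)
    ytr_all <- as.integer(split$train$group == "malignant")
    Xte <- feature_matrix(split$test)
    yte <- as.integer(split$test$group == "malignant")
    for (m in seq_along(models)) {
      spec <- models[[m]]
      conf <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      for (r in seq_len(n_reps)) {
        folds <- stratified_folds(split$train$group, n_folds,
                                  seed = derive_seed(seed, r))
        for (k in seq_len(n_folds)) {
          tr <- folds != k
          sc <- fit_scaler(Xtr_all[tr, , drop = FALSE])
          fit <- fit_model(spec, apply_scaler(Xtr_all[tr, , drop = FALSE], sc),
                           ytr_all[tr],
                           seed = derive_seed(seed, 1000L * m + 10L * r + k))
          s <- predict_scores(fit, apply_scaler(Xtr_all[!tr, , drop = FALSE], sc))
          yv <- ytr_all[!tr]
          pred <- as.integer(s >= 0.5)
          tp <- sum(pred == 1 & yv == 1); fp <- sum(pred == 1 & yv == 0)
          tn <- sum(pred == 0 & yv == 0); fn <- sum(pred == 0 & yv == 1)
          conf <- conf + c(tp = tp, fp = fp, tn = tn, fn = fn)
          panel <- suppressMessages(
            metrics_from_confusion(tp, fp, tn, fn, scores = s, labels = yv == 1))
          cv_rows[[length(cv_rows) + 1L]] <- data.frame(
            representation = rep_name, model = spec$model, repetition = r,
            fold = k, tp = tp, fp = fp, tn = tn, fn = fn, t(panel))
        }
      }
      pooled[[paste(rep_name, spec$model)]] <- conf
      # final refit on the full training partition, held-out evaluation
      sc <- fit_scaler(Xtr_all)
      fit <- fit_model(spec, apply_scaler(Xtr_all, sc), ytr_all,
                       seed = derive_seed(seed, 1000L * m))
      s_te <- predict_scores(fit, apply_scaler(Xte, sc))
      pred <- as.integer(s_te >= 0.5)
      tp <- sum(pred == 1 & yte == 1); fp <- sum(pred == 1 & yte == 0)
      tn <- sum(pred == 0 & yte == 0); fn <- sum(pred == 0 & yte == 1)
      panel <- suppressMessages(
        metrics_from_confusion(tp, fp, tn, fn, scores = s_te, labels = yte == 1))
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        representation = rep_name, model = spec$model,
        tp = tp, fp = fp, tn = tn, fn = fn, t(panel))
      rocs[[paste(rep_name, spec$model)]] <-
        roc_analysis(s_te, yte == 1)
    }
  }
  cv <- do.call(rbind, cv_rows)
  agg_mean <- stats::aggregate(
    cv[, c("sensitivity", "specificity", "ppv", "npv", "plr", "nlr",
           "accuracy", "auc")],
    by = cv[, c("representation", "model")],
    FUN = function(v) mean(v, na.rm = TRUE))
  agg_sd <- stats::aggregate(
    cv[, c("sensitivity", "specificity", "ppv", "npv", "plr", "nlr",
           "accuracy", "auc")],
    by = cv[, c("representation", "model")],
    FUN = function(v) sd(v, na.rm = TRUE))
  names(agg_sd)[-(1:2)] <- paste0(names(agg_sd)[-(1:2)], "_sd")
  pooled_metrics <- do.call(rbind, lapply(names(pooled), function(nm) {
    cf <- pooled[[nm]]
    data.frame(key = nm, t(suppressMessages(
      metrics_from_confusion(cf["tp"], cf["fp"], cf["tn"], cf["fn"]))))
  }))
  structure(list(cv = cv, cv_summary = merge(agg_mean, agg_sd),
                 pooled_confusion = pooled, pooled_metrics = pooled_metrics,
                 test = do.call(rbind, test_rows), test_roc = rocs,
                 n_folds = n_folds, n_reps = n_reps, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold x %d repetitions, base seed %d\n",
              x$n_folds, x$n_reps, x$seed))
  print(x$cv_summary[, c("representation", "model", "accuracy", "auc")],
        row.names = FALSE)
  invisible(x)
}
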