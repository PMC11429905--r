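#' Partial least squares discriminant analysis (binary)
#'
#' Fits a PLS regression of a 0/1 class response on the feature columns
#' (NIPALS projection via mixOmics, features standardized with training
#' statistics only), classifies at a predicted-response threshold of 0.5,
#' and reports the study's panel: per-class precision/recall/F1 with
#' support, accuracy, macro and weighted averages, test AUC, the training
#' R2 (fraction of response variance explained at `n_components`) and Q2
#' (its cross-validated counterpart, by stratified 10-fold CV on the
#' training set).
#'
#' @param train,test Feature tables restricted to two groups.
#' @param n_components Number of latent components (default 2).
#' @param positive Positive class label (default: the non-control level
#'   present, e.g. "malignant").
#' @param q2_folds Folds for the Q2 cross-validation.
#' @param seed Seed for the Q2 fold shuffle.
#' @return Object of class `plsda_result`: list with `scores` (training
#'   latent variates), `test_scores`, `report` (per-class panel),
#'   `accuracy`, `macro`, `weighted`, `auc`, `r2`, `q2`, `confusion`.
#' @export
fit_plsda <- function(train, test, n_components = 2, positive = NULL,
                      q2_folds = 10, seed = 1) {
  lev <- unique(as.character(c(train$group, test$group)))
  if (length(lev) != 2) stop("fit_plsda: need exactly two groups")
  if (is.null(positive)) positive <- setdiff(lev, "control")[1]
  negative <- setdiff(lev, positive)
  Xtr <- feature_matrix(train)
  ytr <- as.numeric(train$group == positive)
  Xte <- feature_matrix(test)
  yte <- as.numeric(test$group == positive)
  if (length(unique(ytr)) < 2)
    stop("fit_plsda: degenerate response (one class in training data)")
  keep <- apply(Xtr, 2, sd) > 0
  if (!all(keep))
    utfmp_log("classifiers", sprintf("dropping %d zero-variance feature(s) for PLS-DA",
                                     sum(!keep)))
  Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
  rank_cap <- min(nrow(Xtr) - 1L, ncol(Xtr))
  if (n_components > rank_cap)
    stop(sprintf("fit_plsda: dimension error - n_components %d exceeds rank bound %d",
                 n_components, rank_cap))
  fit <- mixOmics::pls(Xtr, matrix(ytr, ncol = 1), ncomp = n_components,
                       mode = "regression", scale = TRUE)
  yhat_tr <- predict(fit, Xtr)$predict[, 1, n_components]
  sst <- sum((ytr - mean(ytr))^2)
  r2 <- 1 - sum((ytr - yhat_tr)^2) / sst
  q2 <- plsda_q2(Xtr, ytr, n_components, q2_folds, seed)
  yhat_te <- predict(fit, Xte)$predict[, 1, n_components]
  pred <- as.integer(yhat_te >= 0.5)
  report <- do.call(rbind, lapply(c(0, 1), function(cl) {
    tp <- sum(pred == cl & yte == cl)
    data.frame(
      class = if (cl == 1) positive else negative,
      precision = if (sum(pred == cl) > 0) tp / sum(pred == cl) else NA_real_,
      recall = tp / sum(yte == cl),
      support = sum(yte == cl))
  }))
  report$f1 <- with(report, ifelse(precision + recall > 0,
                                   2 * precision * recall / (precision + recall), 0))
  report <- report[, c("class", "precision", "recall", "f1", "support")]
  wts <- report$support / sum(report$support)
  macro <- colMeans(report[, c("precision", "recall", "f1")])
  weighted <- colSums(report[, c("precision", "recall", "f1")] * wts)
  auc <- if (length(unique(yte)) == 2) roc_analysis(yhat_te, yte == 1)$auc else NA_real_
  structure(list(
    scores = fit$variates$X, test_scores = predict(fit, Xte)$variates,
    response = list(train = yhat_tr, test = yhat_te),
    report = report, accuracy = mean(pred == yte),
    macro = macro, weighted = weighted, auc = auc, r2 = r2, q2 = q2,
    confusion = c(tp = sum(pred == 1 & yte == 1), fp = sum(pred == 1 & yte == 0),
                  tn = sum(pred == 0 & yte == 0), fn = sum(pred == 0 & yte == 1)),
    positive = positive, n_components = n_components),
    class = "plsda_result")
}

# Cross-validated R2 of the PLS response prediction (PRESS-based Q2).
plsda_q2 <- function(X, y, n_components, k = 10, seed = 1) {
  k <- min(k, min(table(y)))
  folds <- stratified_folds(factor(y), k, seed)
  press <- 0
  for (f in seq_len(k)) {
    tr <- folds != f
    Xf <- X[tr, , drop = FALSE]
    keep <- apply(Xf, 2, sd) > 0
    ncomp <- min(n_components, nrow(Xf) - 1L, sum(keep))
    fit <- mixOmics::pls(Xf[, keep, drop = FALSE], matrix(y[tr], ncol = 1),
                         ncomp = ncomp, mode = "regression", scale = TRUE)
    yhat <- predict(fit, X[!tr, keep, drop = FALSE])$predict[, 1, ncomp]
    press <- press + sum((y[!tr] - yhat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("<plsda_result> positive = '%s', %d components\n",
              x$positive, x$n_components))
  cat(sprintf("  accuracy %.3f, AUC %.3f, R2 %.3f, Q2 %.3f\n",
              x$accuracy, x$auc, x$r2, x$q2))
  print(x$report, row.names = FALSE)
  invisible(x)
}
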