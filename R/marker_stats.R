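#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval: with `p = successes/n` and normal quantile
#' `z`, centre `(p + z^2/2n) / (1 + z^2/n)` and half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`. Preferred over the Wald
#' interval for the small per-threshold counts of ROC sweeps.
#'
#' @param successes,n Nonnegative counts, `successes <= n`, `n >= 1`.
#'   Vectorised over `successes` (and `n`).
#' @param confidence Coverage level, default 0.95.
#' @return Data frame with `estimate`, `lower`, `upper`, `n`.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (any(n < 1)) stop("wilson_interval: n must be >= 1")
  if (any(successes < 0) || any(successes > n))
    stop("wilson_interval: successes must lie in [0, n]")
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(estimate = p,
             lower = pmax(center - half, 0),
             upper = pmin(center + half, 1),
             n = n)
}

#' Dunn's rank-sum post hoc test
#'
#' Pairwise z-statistics on mean ranks of the pooled sample with tie
#' correction, the standard follow-up to a Kruskal-Wallis rejection.
#' P-values are two-sided normal and Bonferroni-adjusted over the pairs.
#'
#' @param values Numeric vector.
#' @param groups Factor of group labels (>= 2 levels present).
#' @return Data frame: `pair`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("dunn_test: need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    se <- sqrt(s2 * (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    z <- if (se > 0) (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se else 0
    data.frame(pair = paste(pr, collapse = " vs "), z = z,
               p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p_raw, method = "bonferroni")
  out
}

#' Group-difference test for one feature
#'
#' Implements the study's testing protocol for a zone summary or ratio
#' marker across the three groups. In `auto` mode the Shapiro-Wilk test is
#' run per group at alpha 0.05; any rejection (or degenerate group) routes
#' the variable to Kruskal-Wallis with Dunn/Bonferroni post hoc, otherwise
#' to one-way ANOVA with Tukey HSD. Medians and interquartile ranges are
#' always reported.
#'
#' @param table Feature table with a `group` column.
#' @param variable Feature column name.
#' @param mode `"auto"`, `"nonparametric"` or `"parametric"`.
#' @param alpha Normality-gate significance level.
#' @return Object of class `group_test`: list with `variable`, `test`,
#'   `global_p`, `pairwise` (pair, p_raw where available, p_adj,
#'   adjustment), `summary` (group, n, median, iqr), `normality`.
#' @export
test_group_differences <- function(table, variable,
                                   mode = c("auto", "nonparametric", "parametric"),
                                   alpha = 0.05) {
  mode <- match.arg(mode)
  if (!variable %in% names(table))
    stop(sprintf("test_group_differences: no column '%s'", variable))
  x <- table[[variable]]
  g <- droplevels(as.factor(table$group))
  n_g <- table(g)
  if (length(n_g) < 2)
    stop("test_group_differences: need >= 2 groups")
  if (any(n_g < 3))
    stop(sprintf("test_group_differences: insufficient data - group '%s' has %d < 3 observations",
                 names(n_g)[which.min(n_g)], min(n_g)))
  normality <- NULL
  if (mode == "auto") {
    normality <- vapply(levels(g), function(lv) {
      xs <- x[g == lv]
      if (length(unique(xs)) < 3 || length(xs) > 5000) return(0)
      tryCatch(shapiro.test(xs)$p.value, error = function(e) 0)
    }, numeric(1))
    mode <- if (any(normality < alpha)) "nonparametric" else "parametric"
  }
  summ <- data.frame(group = levels(g), n = as.integer(n_g),
                     median = as.numeric(tapply(x, g, median)),
                     iqr = as.numeric(tapply(x, g, IQR)))
  if (var(x) == 0) {
    # no variation anywhere: degenerate, nothing to test
    pairs <- utils::combn(levels(g), 2, FUN = paste, collapse = " vs ")
    return(structure(list(
      variable = variable, test = "degenerate", global_p = 1,
      pairwise = data.frame(pair = pairs, p_raw = 1, p_adj = 1,
                            adjustment = "none"),
      summary = summ, normality = normality), class = "group_test"))
  }
  if (mode == "nonparametric") {
    kw <- kruskal.test(x, g)
    dn <- dunn_test(x, g)
    pairwise <- data.frame(pair = dn$pair, p_raw = dn$p_raw, p_adj = dn$p_adj,
                           adjustment = "dunn_bonferroni")
    test <- "kruskal_wallis"
    global_p <- kw$p.value
  } else {
    fit <- aov(x ~ g)
    global_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    pairwise <- data.frame(
      pair = gsub("-", " vs ", rownames(tk), fixed = TRUE),
      p_raw = NA_real_, p_adj = tk[, "p adj"], adjustment = "tukey")
    test <- "anova"
  }
  structure(list(variable = variable, test = test, global_p = global_p,
                 pairwise = pairwise, summary = summ, normality = normality),
            class = "group_test")
}

#' Significance stars
#'
#' Star mapping used in the study's figures: `****` p < 0.0001, `***`
#' p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#' @param p P-value(s).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' ROC analysis of a scalar marker
#'
#' Threshold sweep over the unique marker values, with a Wilson score
#' confidence interval for the sensitivity and specificity at every
#' threshold. The AUC is computed by the trapezoidal rule over the sweep
#' (equal to the Mann-Whitney statistic with ties counted half); its
#' standard error, 95% CI and p-value against AUC = 0.5 use the
#' Hanley-McNeil normal approximation. Polarity makes the marker's
#' direction explicit: with `lower_is_positive`, smaller scores indicate
#' the positive class (as for the Z6/Z7 ratio in malignancy).
#'
#' @param scores Numeric marker values, no missing.
#' @param labels Binary labels (logical, or factor/character with
#'   `positive` naming the positive class).
#' @param polarity `"higher_is_positive"` or `"lower_is_positive"`.
#' @param positive Positive-class label when `labels` is not logical.
#' @param confidence Level for all confidence intervals.
#' @return Object of class `roc_result`: list with `sweep` (threshold,
#'   sensitivity/specificity and their Wilson bounds), `auc`, `auc_se`,
#'   `auc_ci_95`, `p_value`, `polarity`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels,
                         polarity = c("higher_is_positive", "lower_is_positive"),
                         positive = NULL, confidence = 0.95) {
  polarity <- match.arg(polarity)
  if (any(is.na(scores))) stop("roc_analysis: missing scores")
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- as.character(labels)
    if (is.null(positive)) {
      u <- sort(unique(labels))
      if (length(u) != 2) stop("roc_analysis: labels must be binary")
      positive <- u[2]
    }
    pos <- labels == positive
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_analysis: both classes must be present")
  s <- if (polarity == "lower_is_positive") -scores else scores
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(s >= t & pos), numeric(1))
  fp <- vapply(thr, function(t) sum(s >= t & !pos), numeric(1))
  sens_ci <- wilson_interval(tp, n_pos, confidence)
  spec_ci <- wilson_interval(n_neg - fp, n_neg, confidence)
  sweep <- data.frame(
    threshold = if (polarity == "lower_is_positive") -thr else thr,
    sensitivity = sens_ci$estimate, sens_lower = sens_ci$lower,
    sens_upper = sens_ci$upper,
    specificity = spec_ci$estimate, spec_lower = spec_ci$lower,
    spec_upper = spec_ci$upper)
  # trapezoid over the full sweep incl. the (0,0) and (1,1) anchors
  fpr <- c(0, fp / n_neg, 1)
  tpr <- c(0, tp / n_pos, 1)
  auc <- pracma::trapz(fpr, tpr)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt(max(0, (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                           (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)))
  z <- qnorm(1 - (1 - confidence) / 2)
  p_value <- if (auc_se > 0) 2 * pnorm(-abs((auc - 0.5) / auc_se)) else
    as.numeric(auc == 0.5)
  structure(list(sweep = sweep, auc = auc, auc_se = auc_se,
                 auc_ci_95 = c(max(auc - z * auc_se, 0), min(auc + z * auc_se, 1)),
                 p_value = p_value, polarity = polarity,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (SE %.4f, 95%% CI %.4f-%.4f, p = %.3g), %d pos / %d neg, %s\n",
              x$auc, x$auc_se, x$auc_ci_95[1], x$auc_ci_95[2], x$p_value,
              x$n_pos, x$n_neg, x$polarity))
  invisible(x)
}
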