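#' @name cohort_stats
#' @title Statistical stage of the severity study
#' @description
#' Severity grouping by calcium, normality-gated descriptive summaries and
#' two-group tests, Spearman rank correlation, empirical ROC analysis with
#' DeLong confidence intervals and Youden-index optimal cut-offs, and
#' ICC(2,1) reliability.
NULL

#' Hypercalcemia severity group
#'
#' Mild hypercalcemia is calcium in \[10.5, 11.5) mg/dL, marked is
#' >= 11.5 mg/dL (the two printed conventions, "10.50-11.49" and
#' "exceeding 11.50", agree at 2-decimal resolution under this rule).
#' Calcium below the 10.5 mg/dL cohort-inclusion bound is ineligible and
#' returned as `NA` with a logged message.
#'
#' @param calcium serum calcium, mg/dL.
#' @return factor with levels `mild`, `marked`; `NA` for ineligible values.
#' @export
severity_group <- function(calcium) {
  out <- ifelse(calcium >= 11.5, "marked", ifelse(calcium >= 10.5, "mild", NA))
  n_bad <- sum(is.na(out) & !is.na(calcium))
  if (n_bad > 0) {
    message(sprintf("severity_group: %d record(s) with calcium < 10.5 mg/dL labeled ineligible and excluded", n_bad))
  }
  factor(out, levels = c("mild", "marked"))
}

#' Normality-gated descriptive summary
#'
#' Mean +/- SD for normally distributed data, median (min-max) otherwise,
#' following the study's reporting convention. Normality defaults to a
#' Shapiro-Wilk test at alpha = 0.05.
#'
#' @param values numeric vector (missing values dropped; n >= 2 required).
#' @param normal logical; if `NULL`, decided by Shapiro-Wilk at alpha 0.05.
#' @param digits decimals used by the `format` method.
#' @return list of class `descriptive_summary` with `n`, `normal`, `mean`,
#'   `sd`, `median`, `min`, `max` and a `formatted` string.
#' @export
descriptive_summary <- function(values, normal = NULL, digits = 2) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("descriptive_summary needs at least 2 non-missing values")
  if (is.null(normal)) {
    normal <- length(unique(values)) > 2 &&
      stats::shapiro.test(values)$p.value > 0.05
  }
  out <- list(n = length(values), normal = normal,
              mean = mean(values), sd = stats::sd(values),
              median = stats::median(values), min = min(values), max = max(values))
  out$formatted <- if (normal) {
    sprintf("%.*f ± %.*f", digits, out$mean, digits, out$sd)
  } else {
    sprintf("%s (%s–%s)", format(round(out$median, digits)),
            format(round(out$min, digits)), format(round(out$max, digits)))
  }
  class(out) <- "descriptive_summary"
  out
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(x$formatted, sprintf(" [n=%d, %s]\n", x$n,
                           if (x$normal) "mean ± SD" else "median (min–max)"))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; the p-value uses the t approximation
#' with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `rho`, `p`, `n`; `rho` is `NA` (with a warning) when
#'   either variable has zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_rho needs at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk (alpha 0.05) on each group selects the test: when both
#' groups are compatible with normality an independent t-test is used, with
#' equal variances decided by Levene's test (alpha 0.05, mean-centred);
#' otherwise a two-sided Mann-Whitney U test (normal approximation with tie
#' correction and continuity correction). Group summaries follow the same
#' gate: mean +/- SD when the t-test is used, median (min-max) otherwise.
#'
#' @param values numeric outcome.
#' @param groups two-level grouping (factor or coercible); each group needs
#'   n >= 3.
#' @param variable label carried into the result.
#' @return list of class `group_comparison`: `variable`, `test_used` ("t"
#'   or "mann_whitney"), `p_value`, `statistic` (t or U), `normal`,
#'   `group_summaries` (named list of [descriptive_summary()]).
#' @export
compare_groups <- function(values, groups, variable = deparse(substitute(values))) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) != 2) stop("compare_groups needs exactly two groups")
  gs <- split(values, groups)
  if (any(lengths(gs) < 3)) stop("each group needs at least 3 values")
  shapiro_ok <- vapply(gs, function(v) {
    length(unique(v)) > 2 && stats::shapiro.test(v)$p.value > 0.05
  }, logical(1))
  normal <- all(shapiro_ok)
  if (normal) {
    lev <- car::leveneTest(values ~ groups, center = mean)
    equal_var <- lev[["Pr(>F)"]][1] > 0.05
    tt <- stats::t.test(values ~ groups, var.equal = equal_var)
    test_used <- "t"; p <- tt$p.value; statistic <- unname(tt$statistic)
  } else {
    wt <- stats::wilcox.test(values ~ groups, exact = FALSE, correct = TRUE)
    test_used <- "mann_whitney"; p <- wt$p.value; statistic <- unname(wt$statistic)
  }
  out <- list(variable = variable, test_used = test_used, p_value = p,
              statistic = statistic, normal = normal,
              group_summaries = lapply(gs, descriptive_summary, normal = normal))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s, %s test, p %s\n", x$variable,
              x$group_summaries[[1]]$formatted, x$group_summaries[[2]]$formatted,
              x$test_used, format_p(x$p_value)))
  invisible(x)
}

#' Format a p-value in the study's reporting style
#'
#' Values below 0.001 print as `"<0.001"`; exact values are kept in machine
#' output.
#' @param p numeric p-value(s).
#' @param digits decimals for printable values.
#' @export
format_p <- function(p, digits = 3) {
  ifelse(is.na(p), "NA", ifelse(p < 0.001, "<0.001", sprintf("%.*f", digits, p)))
}

# DeLong placements and variance for the empirical AUC.
delong_variance <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(pos, function(a) mean(psi(a, neg)), numeric(1))
  V01 <- vapply(neg, function(b) mean(psi(pos, b)), numeric(1))
  auc <- mean(V10)
  s10 <- if (m > 1) stats::var(V10) else 0
  s01 <- if (n > 1) stats::var(V01) else 0
  list(auc = auc, se = sqrt(s10 / m + s01 / n))
}

#' Empirical ROC curve with DeLong inference
#'
#' Builds the empirical ROC over all distinct thresholds, computes the
#' trapezoid AUC (identical to the tie-corrected Mann-Whitney statistic
#' U/(n1*n2)), a DeLong 95% confidence interval, and the DeLong test of
#' AUC = 0.5. With `direction = "auto"` the direction is chosen so that
#' AUC >= 0.5.
#'
#' @param marker numeric marker values.
#' @param labels two-level class labels; the positive class is the second
#'   level of `factor(labels)` unless `positive` names it.
#' @param direction `"auto"`, `"greater_is_positive"` or
#'   `"lesser_is_positive"`.
#' @param positive optional positive-class label.
#' @param conf_level confidence level for the AUC interval.
#' @return object of class `roc_result`: `auc`, `auc_ci95`, `se`,
#'   `p_value`, `direction`, `curve` (data.frame fpr/tpr/threshold),
#'   `marker`, `positive` (logical vector).
#' @export
roc_curve <- function(marker, labels,
                      direction = c("auto", "greater_is_positive", "lesser_is_positive"),
                      positive = NULL, conf_level = 0.95) {
  direction <- match.arg(direction)
  ok <- !is.na(marker) & !is.na(labels)
  marker <- marker[ok]
  labels <- droplevels(factor(labels[ok]))
  if (nlevels(labels) != 2) stop("roc_curve needs both classes present")
  if (is.null(positive)) positive <- levels(labels)[2]
  is_pos <- labels == positive
  build <- function(score) {
    thr <- sort(unique(score), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(score[is_pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(score[!is_pos] >= t), numeric(1))
    data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  }
  auc_trap <- function(curve) {
    sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  }
  if (direction == "auto") {
    direction <- if (auc_trap(build(marker)) >= 0.5) "greater_is_positive" else "lesser_is_positive"
  }
  score <- if (direction == "greater_is_positive") marker else -marker
  curve <- build(score)
  if (direction == "lesser_is_positive") curve$threshold <- -curve$threshold
  auc <- auc_trap(curve)
  dl <- delong_variance(score[is_pos], score[!is_pos])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (dl$se > 0) pmin(pmax(c(auc - z * dl$se, auc + z * dl$se), 0), 1) else c(auc, auc)
  p <- if (dl$se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / dl$se) else as.numeric(auc == 0.5)
  out <- list(auc = auc, auc_ci95 = ci, se = dl$se, p_value = p,
              direction = direction,
              curve = curve, marker = marker, positive = is_pos)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (95%% CI %.3f-%.3f), p %s, %s\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], format_p(x$p_value), x$direction))
  invisible(x)
}

#' Youden index
#'
#' `J = sensitivity + specificity - 1`.
#' @param sensitivity,specificity fractions in \[0, 1\].
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must be in [0, 1]")
  }
  sensitivity + specificity - 1
}

#' Youden-optimal cut-off of a ROC result
#'
#' Enumerates realized marker values as candidate cut-offs (classification
#' rule `marker > c`, or `marker < c` when lesser values indicate the
#' positive class) and returns the cut-off maximizing J. Ties are broken by
#' higher sensitivity, then by the cut-off nearest the marker median, then
#' by the smaller cut-off. A constant marker yields J = 0 and is flagged
#' degenerate.
#'
#' @param roc a [roc_curve()] result.
#' @return list: `cutoff`, `rule` (e.g. `">2.54"`), `sensitivity`,
#'   `specificity`, `youden_j`, `degenerate`.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  marker <- roc$marker; is_pos <- roc$positive
  greater <- roc$direction == "greater_is_positive"
  cand <- sort(unique(marker))
  eval_cut <- function(c0) {
    pred <- if (greater) marker > c0 else marker < c0
    se <- mean(pred[is_pos]); sp <- mean(!pred[!is_pos])
    c(se = se, sp = sp, j = se + sp - 1)
  }
  stats_mat <- t(vapply(cand, eval_cut, numeric(3)))
  med <- stats::median(marker)
  ord <- order(-stats_mat[, "j"], -stats_mat[, "se"], abs(cand - med), cand)
  best <- ord[1]
  list(cutoff = cand[best],
       rule = sprintf("%s%g", if (greater) ">" else "<", cand[best]),
       sensitivity = unname(stats_mat[best, "se"]),
       specificity = unname(stats_mat[best, "sp"]),
       youden_j = unname(stats_mat[best, "j"]),
       degenerate = max(stats_mat[, "j"]) <= 0)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' standard two-way ANOVA mean-square decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings complete numeric matrix, subjects in rows (n >= 5),
#'   raters in columns (k >= 2). Missing cells are an error (no imputation).
#' @return list with `icc`, `ms` (MSR, MSC, MSE), `n`, `k`.
#' @export
icc21 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("icc21 requires a complete ratings matrix (no imputation)")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("icc21 needs >= 5 subjects and >= 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k)
}
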