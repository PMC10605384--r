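#' Run the full cohort statistical analysis
#'
#' Reproduces the statistical stage of the severity study on a cohort
#' table: (1) descriptive summaries of labs and imaging parameters,
#' (2) the Spearman correlation matrix between functional markers and
#' imaging parameters with per-cell n, (3) the mild-vs-marked severity
#' comparison with normality-gated tests, (4) the ROC / Youden cut-off
#' table for predicting marked hypercalcemia and (5) the lower-right vs
#' lower-left adenoma-location comparison when location labels are present.
#'
#' @param cohort a `cohort_table` (or data.frame) with columns `pth`,
#'   `calcium`, `phosphorus`, `vitd`, `elbr`, `eltr`, `dlbr`, `dltr`, `ri`,
#'   `svol`, `pth_svol` (the last two may be partly missing), optionally
#'   `severity` (recomputed from calcium if absent) and `location_label`.
#' @param config optional list: `alpha` (default 0.05), `bh_annotate`
#'   (default FALSE; adds Benjamini-Hochberg adjusted p columns alongside,
#'   never replacing, the raw p-values).
#' @return list of class `study_report` with elements `descriptives`,
#'   `correlations`, `severity_comparison`, `roc_table`,
#'   `location_comparison` (NULL when labels are absent), `n`.
#' @export
run_study_analysis <- function(cohort, config = list()) {
  alpha <- config$alpha %||% 0.05
  bh <- isTRUE(config$bh_annotate)
  lab_vars <- c(pth = "Parathormone (ng/L)", calcium = "Calcium (mg/dL)",
                phosphorus = "Phosphorus (mg/dL)", vitd = "25(OH) vitamin D (ug/L)")
  img_vars <- c(elbr = "eLBR", eltr = "eLTR", dlbr = "dLBR", dltr = "dLTR",
                ri = "RI", svol = "Svol (cm^3)", pth_svol = "PTH/Svol (ng/L/cm^3)")
  need <- c(names(lab_vars), names(img_vars))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(cohort$severity)) cohort$severity <- severity_group(cohort$calcium)
  eligible <- !is.na(cohort$severity)
  if (!all(eligible)) {
    message(sprintf("run_study_analysis: excluding %d ineligible record(s)", sum(!eligible)))
    cohort <- cohort[eligible, ]
  }

  # (1) descriptives
  descriptives <- do.call(rbind, lapply(need, function(v) {
    s <- descriptive_summary(cohort[[v]])
    data.frame(variable = v, label = unname(c(lab_vars, img_vars)[v]), n = s$n,
               summary_type = if (s$normal) "mean_sd" else "median_range",
               formatted = s$formatted, mean = s$mean, sd = s$sd,
               median = s$median, min = s$min, max = s$max,
               stringsAsFactors = FALSE)
  }))

  # (2) correlations: functional markers and imaging parameters vs imaging
  cor_rows <- c(names(lab_vars), "elbr", "eltr", "dlbr", "dltr", "ri", "svol")
  cor_cols <- c("svol", "pth_svol", "elbr", "dlbr", "ri")
  correlations <- do.call(rbind, lapply(cor_rows, function(a) {
    do.call(rbind, lapply(cor_cols, function(b) {
      if (a == b) return(NULL)
      ok <- stats::complete.cases(cohort[[a]], cohort[[b]])
      if (sum(ok) < 4) return(NULL)
      s <- spearman_rho(cohort[[a]][ok], cohort[[b]][ok])
      data.frame(var1 = a, var2 = b, n = s$n, rho = s$rho, p = s$p,
                 p_formatted = format_p(s$p), stringsAsFactors = FALSE)
    }))
  }))
  if (bh) correlations$p_bh <- stats::p.adjust(correlations$p, "BH")

  # (3) severity comparison
  cmp_vars <- setdiff(need, "calcium")
  severity_comparison <- do.call(rbind, lapply(cmp_vars, function(v) {
    ok <- !is.na(cohort[[v]])
    if (min(table(cohort$severity[ok])) < 3) return(NULL)
    g <- compare_groups(cohort[[v]][ok], cohort$severity[ok], variable = v)
    data.frame(variable = v, n_mild = g$group_summaries$mild$n,
               n_marked = g$group_summaries$marked$n,
               mild = g$group_summaries$mild$formatted,
               marked = g$group_summaries$marked$formatted,
               test_used = g$test_used, p = g$p_value,
               p_formatted = format_p(g$p_value), stringsAsFactors = FALSE)
  }))
  if (bh) severity_comparison$p_bh <- stats::p.adjust(severity_comparison$p, "BH")

  # (4) ROC / Youden table for marked hypercalcemia
  roc_table <- do.call(rbind, lapply(cmp_vars, function(v) {
    ok <- !is.na(cohort[[v]])
    if (length(unique(cohort$severity[ok])) < 2) return(NULL)
    r <- roc_curve(cohort[[v]][ok], cohort$severity[ok], positive = "marked")
    yc <- youden_optimal_cutoff(r)
    data.frame(variable = v, n = sum(ok), auc = r$auc,
               ci_lo = r$auc_ci95[1], ci_hi = r$auc_ci95[2],
               p = r$p_value, p_formatted = format_p(r$p_value),
               cutoff = yc$cutoff, rule = yc$rule,
               sensitivity_pct = 100 * yc$sensitivity,
               specificity_pct = 100 * yc$specificity,
               youden_j = yc$youden_j, stringsAsFactors = FALSE)
  }))

  # (5) location comparison (lower right vs lower left), when labelled
  location_comparison <- NULL
  if (!is.null(cohort$location_label)) {
    keep <- cohort$location_label %in% c("lower_right", "lower_left")
    sub <- cohort[keep, ]
    if (nrow(sub) >= 6 && min(table(sub$location_label)) >= 3) {
      location_comparison <- do.call(rbind, lapply(need, function(v) {
        ok <- !is.na(sub[[v]])
        if (min(table(factor(sub$location_label[ok]))) < 3) return(NULL)
        g <- compare_groups(sub[[v]][ok], sub$location_label[ok], variable = v)
        data.frame(variable = v,
                   lower_left = g$group_summaries$lower_left$formatted,
                   lower_right = g$group_summaries$lower_right$formatted,
                   test_used = g$test_used, p = g$p_value,
                   p_formatted = format_p(g$p_value), stringsAsFactors = FALSE)
      }))
    } else {
      message("run_study_analysis: too few labelled lower-pole adenomas; location block skipped")
    }
  } else {
    message("run_study_analysis: no location labels; location block skipped")
  }

  out <- list(descriptives = descriptives, correlations = correlations,
              severity_comparison = severity_comparison, roc_table = roc_table,
              location_comparison = location_comparison,
              n = nrow(cohort), alpha = alpha)
  class(out) <- "study_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report on %d patients\n", x$n))
  cat(sprintf("  descriptives: %d variables\n", nrow(x$descriptives)))
  cat(sprintf("  correlations: %d pairs\n", nrow(x$correlations)))
  cat(sprintf("  severity comparison: %d variables\n", nrow(x$severity_comparison)))
  cat(sprintf("  ROC table: %d markers\n", nrow(x$roc_table)))
  cat(sprintf("  location comparison: %s\n",
              if (is.null(x$location_comparison)) "skipped" else
                sprintf("%d variables", nrow(x$location_comparison))))
  invisible(x)
}
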