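test_that("severity grouping applies the calcium rule with the documented boundary", {
  expect_equal(as.character(severity_group(11.0)), "mild")
  expect_equal(as.character(severity_group(11.6)), "marked")
  # boundary: 11.5 exactly is marked, consistent with the printed
  # 10.50-11.49 vs >11.50 convention at 2-decimal resolution
  expect_equal(as.character(severity_group(11.5)), "marked")
  expect_equal(as.character(severity_group(11.49)), "mild")
  expect_message(g <- severity_group(c(9.8, 10.5, 12)), "ineligible")
  expect_true(is.na(g[1]))
  expect_equal(as.character(g[2:3]), c("mild", "marked"))
})

test_that("descriptive summaries are normality-gated", {
  s <- descriptive_summary(c(1, 2, 3), normal = TRUE)
  expect_equal(s$mean, 2); expect_equal(s$sd, 1)
  expect_equal(s$formatted, "2.00 ± 1.00")
  s2 <- descriptive_summary(c(1, 2, 100), normal = FALSE)
  expect_equal(s2$median, 2)
  expect_match(s2$formatted, "^2 \\(1–100\\)$")
  expect_error(descriptive_summary(c(NA, NA, 3)), "at least 2")
  # simulated lognormal column vs an independent quantile oracle
  set.seed(4); x <- rlnorm(500, 2, 0.6)
  s3 <- descriptive_summary(x)
  expect_false(s3$normal)
  expect_equal(s3$median, sort(x)[c(250, 251)] |> mean(), tolerance = 1e-12)
  expect_equal(s3$min, min(x)); expect_equal(s3$max, max(x))
})

test_that("spearman_rho equals the rank-then-Pearson oracle and handles monotone maps", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  set.seed(11)
  x <- sample(1:5, 10, replace = TRUE); y <- sample(1:5, 10, replace = TRUE)
  s <- spearman_rho(x, y)
  expect_equal(s$rho, spearman_oracle(x, y), tolerance = 1e-12)
  expect_equal(s$rho, suppressWarnings(cor.test(x, y, method = "spearman")$estimate[[1]]),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(x), log(y + 1))$rho, s$rho, tolerance = 1e-12)
  expect_warning(spearman_rho(rep(2, 6), 1:6), "zero rank variance")
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("compare_groups gates the test on normality and matches a U oracle", {
  # identical groups: null identity
  set.seed(2); v <- rnorm(20)
  g0 <- compare_groups(c(v, v), rep(c("a", "b"), each = 20))
  expect_gt(g0$p_value, 0.9)
  # well-separated normal samples select the t-test
  set.seed(3)
  g1 <- compare_groups(c(rnorm(25), rnorm(25, 8)), rep(c("a", "b"), each = 25))
  expect_equal(g1$test_used, "t")
  expect_lt(g1$p_value, 0.001)
  # skewed data select Mann-Whitney; U matches the all-pairs counting oracle
  x <- c(1, 1, 2, 2, 3, 50, 60, 80, 4, 2, 1, 90)
  grp <- rep(c("a", "b"), each = 6)
  g2 <- compare_groups(x, grp)
  expect_equal(g2$test_used, "mann_whitney")
  ua <- sum(outer(x[1:6], x[7:12], function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(g2$statistic, ua)
  expect_error(compare_groups(c(1, 2, 1, 2, 3), c("a", "a", "b", "b", "b")),
               "at least 3")
})

test_that("trapezoid AUC equals the tie-corrected U statistic on random instances", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    x <- sample(1:6, n, replace = TRUE) + round(rnorm(n), 1)
    y <- c("a", "b", sample(c("a", "b"), n - 2, replace = TRUE))
    r <- roc_curve(x, factor(y), direction = "greater_is_positive", positive = "b")
    expect_equal(r$auc, u_statistic_oracle(x[y == "b"], x[y == "a"]), tolerance = 1e-12)
  }
})

test_that("ROC extremes and direction symmetry behave as expected", {
  y <- factor(rep(c("neg", "pos"), each = 10))
  expect_equal(roc_curve(c(1:10, 11:20), y, positive = "pos")$auc, 1.0)
  set.seed(5)
  r0 <- roc_curve(rnorm(2000), factor(rbinom(2000, 1, 0.5)))
  expect_lt(abs(r0$auc - 0.5), 0.06)
  # reversing direction maps AUC -> 1 - AUC
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4)
  rg <- roc_curve(x, y, direction = "greater_is_positive", positive = "pos")
  rl <- roc_curve(x, y, direction = "lesser_is_positive", positive = "pos")
  expect_equal(rg$auc + rl$auc, 1, tolerance = 1e-12)
  expect_error(roc_curve(1:5, factor(rep("a", 5))), "both classes")
  # curve endpoints and monotonicity
  expect_equal(rg$curve$fpr[1], 0); expect_equal(rg$curve$tpr[1], 0)
  expect_equal(tail(rg$curve$fpr, 1), 1); expect_equal(tail(rg$curve$tpr, 1), 1)
  expect_true(all(diff(rg$curve$fpr) >= 0))
  expect_true(all(diff(rg$curve$tpr) >= 0))
})

test_that("DeLong interval and p-value agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  x <- rnorm(80); y <- factor(rep(c("a", "b"), 40)); x[y == "b"] <- x[y == "b"] + 0.8
  r <- roc_curve(x, y, positive = "b")
  pr <- pROC::roc(y, x, direction = "<", levels = c("a", "b"), quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$auc_ci95, ci[c(1, 3)], tolerance = 1e-9)
})

test_that("youden_index reproduces printed worked examples and bounds", {
  expect_equal(round(youden_index(0.6842, 0.8000), 2), 0.48)
  expect_equal(round(youden_index(0.85, 0.60), 2), 0.45)
  expect_equal(youden_index(1, 1), 1)
  expect_error(youden_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("youden_optimal_cutoff matches exhaustive enumeration and its tie rules", {
  # separable data: J = 1, tie rule picks deterministically
  y <- factor(rep(c("a", "b"), each = 5))
  r <- roc_curve(c(1:5, 11:15), y, positive = "b")
  yc <- youden_optimal_cutoff(r)
  expect_equal(yc$youden_j, 1)
  expect_equal(yc$cutoff, 5) # realized value nearest the median among J-ties
  # toy 8-point marker vs exhaustive enumeration oracle
  x <- c(2, 2, 3, 5, 5, 7, 8, 9)
  lab <- factor(c("a", "a", "b", "a", "b", "b", "a", "b"))
  r2 <- roc_curve(x, lab, direction = "greater_is_positive", positive = "b")
  yc2 <- youden_optimal_cutoff(r2)
  best <- -Inf; best_c <- NA
  for (c0 in sort(unique(x))) {
    se <- mean(x[lab == "b"] > c0); sp <- mean(x[lab == "a"] <= c0)
    if (se + sp - 1 > best + 1e-12) { best <- se + sp - 1; best_c <- c0 }
  }
  expect_equal(yc2$youden_j, best, tolerance = 1e-12)
  expect_equal(yc2$cutoff, best_c)
  expect_equal(yc2$youden_j, yc2$sensitivity + yc2$specificity - 1, tolerance = 1e-12)
  # degenerate constant marker: J = 0, flagged
  r3 <- roc_curve(rep(4, 10), y, positive = "b")
  yc3 <- youden_optimal_cutoff(r3)
  expect_equal(yc3$youden_j, 0)
  expect_true(yc3$degenerate)
})

test_that("ICC(2,1) matches the from-scratch ANOVA mean-squares oracle", {
  expect_equal(icc21(cbind(1:8, 1:8, 1:8))$icc, 1.0)
  set.seed(13)
  m <- matrix(rnorm(400), 200, 2) # independent raters: ICC near 0
  expect_lt(abs(icc21(m)$icc), 0.15)
  # 6x2 toy matrix vs aov-based decomposition
  toy <- matrix(c(9, 8, 6, 5, 8, 9, 7, 6, 10, 9, 6, 4), 6, 2, byrow = TRUE)
  fit <- summary(aov(y ~ s + r, data = data.frame(
    y = as.vector(toy), s = factor(rep(1:6, 2)), r = factor(rep(1:2, each = 6))
  )))[[1]]
  ms <- fit[["Mean Sq"]] # terms in order: subject, rater, residual
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + (2 - 1) * mse + 2 * (msc - mse) / 6)
  expect_equal(icc21(toy)$icc, oracle, tolerance = 1e-10)
  expect_error(icc21(matrix(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), 5, 2)), "complete")
  expect_error(icc21(matrix(1:8, 4, 2)), "subjects")
})
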