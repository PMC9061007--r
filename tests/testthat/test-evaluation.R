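test_that("confusion counts match hand enumeration", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc), c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect[["FP"]], 0L)
  expect_equal(perfect[["FN"]], 0L)
  allpos <- confusion_counts(c(0, 0, 0), c(1, 1, 1))
  expect_equal(allpos[["TP"]], 0L)
  expect_equal(allpos[["TN"]], 0L)
  expect_equal(sum(unclass(allpos)), 3L)
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("metric formulas and undefined-denominator policy hold", {
  m <- classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
  expect_equal(as.numeric(m), rep(0.5, 5))
  expect_named(m, c("accuracy", "sensitivity", "specificity", "precision",
                    "f1"))
  p <- classification_metrics(confusion_counts(c(1, 0), c(1, 0)))
  expect_equal(as.numeric(p), rep(1, 5))
  # no predicted positives: precision undefined, not zero
  u <- classification_metrics(confusion_counts(c(1, 1, 0), c(0, 0, 0)))
  expect_equal(u[["sensitivity"]], 0)
  expect_true(is.na(u[["precision"]]))
  expect_true("precision" %in% attr(u, "undefined"))
  expect_equal(u[["accuracy"]], 1 / 3)
})

test_that("metrics agree with a brute-force recount on random vectors", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(2:100, 1)
    lab <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(lab, pred)
    expect_equal(cc[["TP"]], sum(lab == 1 & pred == 1))
    expect_equal(cc[["TN"]], sum(lab == 0 & pred == 0))
    m <- classification_metrics(cc)
    expect_equal(m[["accuracy"]], mean(lab == pred))
    if (any(lab == 1)) {
      expect_equal(m[["sensitivity"]], sum(pred == 1 & lab == 1) / sum(lab == 1))
    }
  }
})

test_that("AUC equals the pair-ordering fraction and handles extremes", {
  labs <- c(rep(0, 5), rep(1, 5))
  expect_equal(roc_auc(labs, c(1:5, 11:15))$auc, 1)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
    score <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(roc_auc(lab, score)$auc, pair_order_auc(lab, score))
  }
  expect_error(roc_auc(rep(1, 4), rnorm(4)), "both classes")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(1)
  n <- 400
  lab <- rbinom(n, 1, 0.4)
  score <- rnorm(n)
  auc <- roc_auc(lab, score)$auc
  n1 <- sum(lab); n0 <- n - n1
  # exact null standard error of the Mann-Whitney AUC
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("ROC curve coordinates are (1 - specificity, sensitivity)", {
  lab <- c(0, 0, 1, 1, 0, 1)
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.9)
  r <- roc_auc(lab, sc)
  expect_true(all(r$fpr >= 0 & r$fpr <= 1))
  expect_true(all(r$tpr >= 0 & r$tpr <= 1))
  # sweep endpoints: all-negative and all-positive thresholds
  expect_true(any(r$fpr == 0 & r$tpr == 0))
  expect_true(any(r$fpr == 1 & r$tpr == 1))
})

test_that("paired t-test matches the textbook computation", {
  a <- c(0.9, 0.8, 0.95, 0.85, 0.9)
  b <- c(0.7, 0.75, 0.8, 0.72, 0.78)
  res <- paired_metric_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, p_hand)
  expect_equal(res$df, 4)
  expect_false(res$degenerate)
})

test_that("zero-variance differences are flagged degenerate", {
  expect_true(paired_metric_test(1:5, 1:5)$degenerate)
  res <- paired_metric_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_true(res$degenerate)
  expect_equal(res$mean_diff, -1)
  expect_true(is.na(res$p_value))
})

test_that("Holm-Bonferroni matches the step-down formula", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  # direct evaluation: sort, multiply k-th smallest by (N - k + 1),
  # enforce monotonicity, cap at 1, restore order
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    n <- length(p)
    o <- order(p)
    direct <- pmin(cummax((n - seq_len(n) + 1) * p[o]), 1)[order(o)]
    expect_equal(holm_bonferroni(p), direct)
    expect_true(all(holm_bonferroni(p) >= p))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm correction never rejects more than uncorrected tests", {
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(2:10, 1), 0, 0.2)
    expect_lte(sum(holm_bonferroni(p) < 0.05), sum(p < 0.05))
  }
})
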