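# Evaluation: confusion-matrix metrics, ROC/AUC, paired two-sided t-tests
# between per-fold metric series, and Holm-Bonferroni correction.

#' Confusion counts for binary predictions
#'
#' Counts true/false positives/negatives with the symptomatic class (label 1)
#' as the positive class.
#'
#' @param labels Vector of true labels in \{0, 1\}.
#' @param predictions Vector of predicted labels in \{0, 1\}, same length.
#' @param positive The positive-class label.
#' @return Object of class `confusion_counts`: named integer vector
#'   `TP, FP, TN, FN` summing to `length(labels)`.
#' @export
confusion_counts <- function(labels, predictions, positive = 1L) {
  if (length(labels) != length(predictions)) {
    stop_config("labels (%d) and predictions (%d) differ in length",
                length(labels), length(predictions))
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop_config("labels and predictions must be binary (0/1)")
  }
  pos <- labels == positive
  ppos <- predictions == positive
  structure(
    c(TP = sum(pos & ppos), FP = sum(!pos & ppos),
      TN = sum(!pos & !ppos), FN = sum(pos & !ppos)),
    class = "confusion_counts"
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1
#' `2*precision*recall/(precision+recall)` with recall = sensitivity.
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' silently 0, and the affected names are listed in the `"undefined"`
#' attribute — this keeps fold averages honest.
#'
#' @param counts A [confusion_counts()] result.
#' @return Object of class `metric_set`: named numeric vector `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop_config("no cases to evaluate")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  m <- c(accuracy = (tp + tn) / total, sensitivity = sens,
         specificity = spec, precision = prec, f1 = f1)
  structure(m, undefined = names(m)[is.na(m)], class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, 4))
  und <- attr(x, "undefined")
  if (length(und)) cat("undefined (zero denominator):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the observed scores to produce the (FPR, TPR)
#' curve with FPR = 1 - specificity and TPR = sensitivity, and the
#' trapezoidal area under it (computed via pROC). Higher scores must mean
#' more symptomatic; both classes must be present.
#'
#' @param labels Binary labels (1 = symptomatic = positive).
#' @param scores Real-valued scores, e.g. `score_symptomatic` from
#'   [osfp_cv()] predictions.
#' @return Object of class `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop_config("labels and scores differ in length")
  }
  if (length(unique(labels)) < 2) {
    stop_config("ROC requires both classes present")
  }
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  structure(
    list(thresholds = r$thresholds, fpr = 1 - r$specificities,
         tpr = r$sensitivities, auc = as.numeric(r$auc)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, AUC = %.4f\n", length(x$thresholds), x$auc))
  invisible(x)
}

#' Paired two-sided t-test between two per-fold metric series
#'
#' Pairs at the fold level (element i of `a` with element i of `b`) and
#' tests whether the mean difference is zero. A zero-variance difference
#' series (e.g. identical fold metrics) makes the t statistic undefined; the
#' result is then flagged `degenerate` with an `NA` p-value rather than a
#' fabricated one.
#'
#' @param a,b Equal-length numeric series (length >= 2), e.g. per-fold
#'   accuracies of two methods.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
paired_metric_test <- function(a, b) {
  if (length(a) != length(b)) stop_config("series must have equal length")
  if (length(a) < 2) stop_config("need at least 2 paired folds")
  d <- a - b
  if (sd(d) < .Machine$double.eps^0.5) {
    return(list(statistic = NA_real_, df = length(d) - 1L,
                p_value = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Holm-Bonferroni step-down correction
#'
#' Multiplies the k-th smallest of N p-values by (N - k + 1), enforces
#' monotone nondecreasing corrected values, caps at 1, and returns them in
#' the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Corrected p-values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_config("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "holm")
}
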