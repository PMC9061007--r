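# Patient-level 5-fold cross-validation (K5 protocol: 80% training / 20%
# testing per round), with fold sizes drawn in a band around n/5 and a
# leakage guard ensuring no (augmented) training variant shares a source
# subject with the test fold.

#' Partition subjects into five patient-level folds
#'
#' Draws five fold sizes within a band and assigns shuffled subjects to the
#' folds, deterministically in `seed`. For 333 subjects the band is
#' \[65, 70\] (a draw such as 66, 66, 66, 66, 69); for other cohort sizes the
#' band scales proportionally (`round(65 n / 333)` to `round(70 n / 333)`).
#' If no size draw can satisfy the band the split falls back to near-equal
#' sizes with a warning.
#'
#' @param subject_ids Character vector of unique subject IDs (length >= 5).
#' @param seed Integer seed.
#' @param k Number of folds.
#' @return An object of class `fold_assignment`: `fold_of` (named integer
#'   vector, values 1..k) and `sizes`.
#' @export
make_folds <- function(subject_ids, seed = 1L, k = 5L) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop_config("subject_ids must be unique")
  if (n < k) stop_config("need at least %d subjects for %d folds", k, k)
  lo <- max(1L, as.integer(round(65 * n / 333)))
  hi <- max(lo, as.integer(round(70 * n / 333)))
  sizes <- with_seed(seed, {
    s <- NULL
    if (k * lo <= n && n <= k * hi) {
      for (try in 1:1000) {
        first <- runif_int(k - 1L, lo, hi)
        last <- n - sum(first)
        if (last >= lo && last <= hi) { s <- c(first, last); break }
      }
    }
    if (is.null(s)) {
      warning(sprintf("no %d fold sizes in [%d, %d] sum to %d; using a near-equal split",
                      k, lo, hi, n), call. = FALSE)
      s <- rep(n %/% k, k)
      extra <- n - sum(s)
      if (extra > 0) s[seq_len(extra)] <- s[seq_len(extra)] + 1L
    }
    s
  })
  order <- with_seed(seed + 1L, sample(n))
  fold_of <- integer(n)
  names(fold_of) <- subject_ids
  fold_of[order] <- rep(seq_len(k), times = sizes)
  structure(list(fold_of = fold_of, sizes = as.integer(sizes)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Patient-level %d-fold assignment of %d subjects; fold sizes %s\n",
              length(x$sizes), length(x$fold_of),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Run patient-level k-fold cross-validation
#'
#' For each of the `k` rounds, holds one fold out as the test set, trains on
#' the remaining subjects (optionally enlarged by subject-consistent
#' augmentation — applied strictly after the split and only to the training
#' side), and scores the held-out subjects. A guard aborts if any training
#' record shares a source subject with the test fold.
#'
#' @param cohort A `plaque_cohort` of unaugmented subjects.
#' @param model An [osfp_config()].
#' @param control A [train_control()]; its seed is offset per fold.
#' @param k Number of folds.
#' @param fold_seed Seed for the fold assignment.
#' @param augment Augment the training split.
#' @param augmentation An [augmentation_spec()] used when `augment = TRUE`.
#' @return An object of class `osfp_cv`: `folds` (the [make_folds()]
#'   assignment), `predictions` (one data frame per fold: `subject_id`,
#'   `label`, `score_symptomatic`, `pred`, `fold`), `metrics` (per-fold
#'   [classification_metrics()] plus AUC), `mean_metrics`, and the per-fold
#'   fits' histories.
#' @export
osfp_cv <- function(cohort, model = osfp_config(), control = train_control(),
                    k = 5L, fold_seed = 1L, augment = FALSE,
                    augmentation = augmentation_spec()) {
  ids <- vapply(cohort, `[[`, "", "subject_id")
  if (any(ids != base_subject_id(ids))) {
    stop_config("cross-validation expects an unaugmented cohort; augmentation is applied per round")
  }
  folds <- make_folds(ids, seed = fold_seed, k = k)
  predictions <- vector("list", k)
  metrics <- vector("list", k)
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds$fold_of[ids] == f)
    train_set <- cohort[-test_idx]
    test_set <- cohort[test_idx]
    if (augment) train_set <- augment_cohort(train_set, augmentation)
    train_src <- base_subject_id(vapply(train_set, `[[`, "", "subject_id"))
    test_src <- vapply(test_set, `[[`, "", "subject_id")
    if (length(intersect(train_src, test_src))) {
      stop_config("leakage: fold %d test subjects present in training set", f)
    }
    ctrl <- control
    ctrl$seed <- control$seed + 100L * f
    fit <- osfp_net(train_set, model = model, control = ctrl,
                    validation = test_set)
    use_w <- fit$best_weights %||% fit$weights
    preds <- do.call(rbind, lapply(subject_batches(test_set), function(b) {
      pr <- softmax(osfp_forward(use_w, b$images, mode = "inference"))
      data.frame(subject_id = b$subject_id, label = b$label,
                 score_symptomatic = pr[2],
                 pred = as.integer(which.max(pr) - 1L), fold = f)
    }))
    predictions[[f]] <- preds
    m <- classification_metrics(confusion_counts(preds$label, preds$pred))
    auc <- if (length(unique(preds$label)) == 2) {
      roc_auc(preds$label, preds$score_symptomatic)$auc
    } else {
      NA_real_
    }
    metrics[[f]] <- c(unclass(m), auc = auc)
    histories[[f]] <- fit$history
  }
  mtab <- do.call(rbind, lapply(metrics, function(m) as.data.frame(as.list(m))))
  mtab$fold <- seq_len(k)
  mean_metrics <- colMeans(mtab[, setdiff(names(mtab), "fold")], na.rm = TRUE)
  structure(
    list(folds = folds, predictions = do.call(rbind, predictions),
         metrics = mtab, mean_metrics = mean_metrics,
         histories = histories, model = model, control = control,
         augmented = isTRUE(augment)),
    class = "osfp_cv"
  )
}

#' @export
print.osfp_cv <- function(x, ...) {
  k <- length(x$histories)
  cat(sprintf("%d-fold patient-level cross-validation (%s augmentation)\n",
              k, if (x$augmented) "with" else "no"))
  cat(sprintf("  fold sizes: %s\n", paste(x$folds$sizes, collapse = ", ")))
  cat("  mean test metrics:\n")
  m <- x$mean_metrics
  cat(sprintf("    %s\n", paste(sprintf("%s %.3f", names(m), m),
                                collapse = "  ")))
  invisible(x)
}

#' @export
summary.osfp_cv <- function(object, ...) {
  cat("Per-fold test metrics:\n")
  print(object$metrics, row.names = FALSE, digits = 3)
  cat("\nMean over folds:\n")
  print(round(object$mean_metrics, 4))
  invisible(object$metrics)
}
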