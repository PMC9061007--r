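# S3 methods for fitted osfp_net objects.

#' @export
print.osfp_net <- function(x, ...) {
  cfg <- x$config
  cat("Object-specific four-path network\n")
  cat(sprintf("  backbone: %d blocks, k = %d channels%s\n",
              cfg$backbone$n_blocks, backbone_k(cfg$backbone),
              if (cfg$backbone$width_scale != 1)
                sprintf(" (width scale %g)", cfg$backbone$width_scale) else ""))
  cat(sprintf("  pooling: SPP %d bins (transverse), MSP %d strips (longitudinal)\n",
              pooling_units(cfg$pooling_transverse),
              pooling_units(cfg$pooling_longitudinal)))
  cat(sprintf("  classifier input: %d; head: %s -> %d\n",
              classifier_input_length(cfg),
              paste(cfg$fc_sizes, collapse = " -> "), cfg$n_classes))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s) on %d subjects; final loss %.4f, running acc %.3f%s\n",
                nrow(x$history), x$n_train, last$loss, last$running_acc,
                if (is.na(last$val_acc)) ""
                else sprintf(", val acc %.3f", last$val_acc)))
  } else {
    cat(sprintf("  untrained (0 epochs); %d subjects supplied\n", x$n_train))
  }
  invisible(x)
}

#' Summary of a fitted four-path network
#'
#' @param object An [osfp_net()] fit.
#' @param ... Unused.
#' @return The per-epoch history data frame, invisibly.
#' @export
summary.osfp_net <- function(object, ...) {
  print(object)
  cfg <- object$config
  n_fe <- length(object$weights$fes)
  fe_params <- backbone_n_params(cfg$backbone)
  sizes <- c(classifier_input_length(cfg), cfg$fc_sizes, cfg$n_classes)
  fc_params <- sum((sizes[-length(sizes)] + 1) * sizes[-1])
  cat(sprintf("  parameters: %d backbone(s) x %s + head %s = %s total\n",
              n_fe, format(fe_params, big.mark = ","),
              format(fc_params, big.mark = ","),
              format(n_fe * fe_params + fc_params, big.mark = ",")))
  if (!is.na(object$best_val_acc)) {
    cat(sprintf("  best validation accuracy %.3f at epoch %d\n",
                object$best_val_acc, object$best_epoch))
  }
  if (nrow(object$history)) {
    cat("\nHistory:\n")
    print(object$history, row.names = FALSE, digits = 4)
  }
  invisible(object$history)
}

#' Predict symptomatic status for new subjects
#'
#' @param object An [osfp_net()] fit.
#' @param newdata A `plaque_cohort` or list of [subject_record()]s.
#' @param type `"class"` for 0/1 labels, `"prob"` for the symptomatic-class
#'   probability, `"score"` for the raw two-column score matrix.
#' @param use_best Use the best-validation-epoch weights when available.
#' @param ... Unused.
#' @return Depending on `type`, a named vector (by subject ID) or matrix.
#' @export
predict.osfp_net <- function(object, newdata,
                             type = c("class", "prob", "score"),
                             use_best = FALSE, ...) {
  type <- match.arg(type)
  w <- if (use_best && !is.null(object$best_weights)) object$best_weights
       else object$weights
  batches <- subject_batches(newdata)
  scores <- t(vapply(batches, function(b)
    osfp_forward(w, b$images, mode = "inference"), numeric(2)))
  ids <- vapply(batches, `[[`, "", "subject_id")
  rownames(scores) <- ids
  colnames(scores) <- c("asymptomatic", "symptomatic")
  switch(type,
    score = scores,
    prob = {
      pr <- apply(scores, 1, function(z) softmax(z)[2])
      names(pr) <- ids
      pr
    },
    class = {
      cl <- as.integer(apply(scores, 1, which.max) - 1L)
      names(cl) <- ids
      cl
    })
}

#' Training-weight list of a fitted network
#'
#' @param object An [osfp_net()] fit.
#' @param ... Unused.
#' @return Nested list of weight matrices: `fes` (per path: per conv layer
#'   `W`, `b`) and `fc` (per head layer `W`, `b`).
#' @export
coef.osfp_net <- function(object, ...) {
  list(fes = lapply(object$weights$fes, function(fe) fe$layers),
       fc = object$weights$fc)
}

#' Plot training curves
#'
#' Base-graphics loss curve with the running training accuracy (and
#' validation accuracy when present) on a secondary axis.
#'
#' @param x An [osfp_net()] fit.
#' @param ... Passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.osfp_net <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "mean cross-entropy loss", main = "osfp_net training", ...)
  graphics::par(new = TRUE)
  plot(h$epoch, h$running_acc, type = "b", pch = 1, lty = 2, col = "grey40",
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  if (any(!is.na(h$val_acc))) {
    graphics::lines(h$epoch, h$val_acc, type = "b", pch = 2, col = "grey60")
  }
  graphics::axis(4)
  graphics::mtext("accuracy", side = 4, line = 2.5)
  invisible(x)
}
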