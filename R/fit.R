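# Training protocol: cross-entropy loss, SGD with momentum at batch size 1
# (heterogeneous input sizes make larger batches impossible without padding),
# and a staircase learning-rate schedule.

#' Training protocol settings
#'
#' Defaults follow the reference protocol: 30 epochs of SGD with momentum
#' 0.9 at batch size 1, initial learning rate 0.001 reduced by a factor of
#' 10 after every 6 epochs, cross-entropy loss.
#'
#' @param epochs Number of passes over the training set.
#' @param lr0 Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param lr_decay_factor Divisor applied at each schedule step.
#' @param lr_decay_every Epochs between schedule steps.
#' @param batch_size Subjects per optimization step; must be 1, since the
#'   four-view inputs of different subjects have different pixel sizes.
#' @param clip_grad_norm Global gradient-norm ceiling applied before each
#'   update (`NULL` disables). Single-subject steps occasionally produce very
#'   large gradients which, amplified by momentum, destabilize training from
#'   scratch; clipping bounds the step without changing its direction.
#' @param seed Seed for weight initialization, epoch shuffles and dropout.
#' @param early_stop_acc Optional training-accuracy threshold in (0, 1];
#'   when the end-of-epoch training accuracy (inference mode) reaches it,
#'   training stops early.
#' @param verbose Print a per-epoch summary line.
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 30L, lr0 = 0.001, momentum = 0.9,
                          lr_decay_factor = 10, lr_decay_every = 6L,
                          batch_size = 1L, clip_grad_norm = 5,
                          seed = 1L,
                          early_stop_acc = NULL, verbose = FALSE) {
  if (batch_size != 1L) {
    stop_config("batch_size must be 1: inputs of heterogeneous sizes cannot be batched")
  }
  if (epochs < 0) stop_config("epochs must be nonnegative")
  structure(
    list(epochs = as.integer(epochs), lr0 = lr0, momentum = momentum,
         lr_decay_factor = lr_decay_factor,
         lr_decay_every = as.integer(lr_decay_every),
         batch_size = 1L, clip_grad_norm = clip_grad_norm,
         seed = as.integer(seed),
         early_stop_acc = early_stop_acc, verbose = isTRUE(verbose)),
    class = "train_control"
  )
}

#' Learning rate at a given epoch
#'
#' Staircase schedule `lr0 / factor^floor(epoch / every)` with 0-based
#' epochs: 0.001 for epochs 0-5, 0.0001 for 6-11, and so on.
#'
#' @param control A [train_control()].
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(control, epoch) {
  stopifnot(inherits(control, "train_control"))
  if (any(epoch < 0 | epoch >= control$epochs)) {
    stop_config("epoch must lie in [0, %d)", control$epochs)
  }
  control$lr0 / control$lr_decay_factor^(epoch %/% control$lr_decay_every)
}

# --- SGD with momentum over the nested weight lists ---------------------

zero_like_weights <- function(weights) {
  zl <- function(layers) lapply(layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  list(fes = lapply(weights$fes, function(fe) zl(fe$layers)),
       fc = zl(weights$fc))
}

# Scale all gradients so the global l2 norm does not exceed max_norm.
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm)) return(grads)
  sq <- 0
  for (f in seq_along(grads$fes)) {
    for (l in seq_along(grads$fes[[f]])) {
      sq <- sq + sum(grads$fes[[f]][[l]]$dW^2) + sum(grads$fes[[f]][[l]]$db^2)
    }
  }
  for (l in seq_along(grads$fc)) {
    sq <- sq + sum(grads$fc[[l]]$dW^2) + sum(grads$fc[[l]]$db^2)
  }
  gn <- sqrt(sq)
  if (!is.finite(gn) || gn <= max_norm) return(grads)
  sc <- max_norm / gn
  for (f in seq_along(grads$fes)) {
    for (l in seq_along(grads$fes[[f]])) {
      grads$fes[[f]][[l]]$dW <- grads$fes[[f]][[l]]$dW * sc
      grads$fes[[f]][[l]]$db <- grads$fes[[f]][[l]]$db * sc
    }
  }
  for (l in seq_along(grads$fc)) {
    grads$fc[[l]]$dW <- grads$fc[[l]]$dW * sc
    grads$fc[[l]]$db <- grads$fc[[l]]$db * sc
  }
  grads
}

# v <- momentum * v - lr * g ; w <- w + v   (applied in place on copies)
sgd_step <- function(weights, grads, velocity, lr, momentum) {
  upd <- function(layer, g, v) {
    v$W <- momentum * v$W - lr * g$dW
    v$b <- momentum * v$b - lr * g$db
    layer$W <- layer$W + v$W
    layer$b <- layer$b + v$b
    list(layer = layer, v = v)
  }
  for (f in seq_along(grads$fes)) {
    for (l in seq_along(grads$fes[[f]])) {
      r <- upd(weights$fes[[f]]$layers[[l]], grads$fes[[f]][[l]],
               velocity$fes[[f]][[l]])
      weights$fes[[f]]$layers[[l]] <- r$layer
      velocity$fes[[f]][[l]] <- r$v
    }
  }
  for (l in seq_along(grads$fc)) {
    r <- upd(weights$fc[[l]], grads$fc[[l]], velocity$fc[[l]])
    weights$fc[[l]] <- r$layer
    velocity$fc[[l]] <- r$v
  }
  list(weights = weights, velocity = velocity)
}

# Inference-mode accuracy of `weights` on a list of batches.
batch_accuracy <- function(weights, batches) {
  ok <- vapply(batches, function(b) {
    s <- osfp_forward(weights, b$images, mode = "inference")
    as.integer(which.max(s) - 1L) == b$label
  }, TRUE)
  mean(ok)
}

#' Fit the four-path network
#'
#' Trains the object-specific four-path classifier on a cohort of subject
#' records: every optimization step consumes one subject's four views
#' (batch size 1), computes softmax cross-entropy against the binary label
#' (class 1 = symptomatic = positive), and updates all path backbones and the
#' head by SGD with momentum under the staircase learning-rate schedule.
#'
#' When a validation cohort is supplied its accuracy is logged every epoch
#' and the weights with the best validation accuracy are retained alongside
#' the final weights. Training and validation subjects must be disjoint (at
#' the source-subject level, so augmented variants cannot leak).
#'
#' @param x A `plaque_cohort` (training records; augment beforehand with
#'   [augment_cohort()] if desired — never augment the validation side).
#' @param model An [osfp_config()]; `osfp_config_tiny()` is the practical
#'   CPU-scale choice.
#' @param control A [train_control()].
#' @param validation Optional `plaque_cohort` of held-out subjects.
#' @param checkpoint Optional pretrained backbone checkpoint, forwarded to
#'   [init_osfp_weights()].
#' @param standardize_init Data-dependent initialization for training from
#'   scratch: before the first epoch, the per-feature mean and spread of the
#'   concatenated descriptor over the *training* subjects is folded into the
#'   first fully connected layer's initial weights, so the classifier starts
#'   from standardized features. This re-chooses only the initial point (no
#'   extra layer; the reachable function class is unchanged) but is what
#'   makes batch-size-1 SGD from random weights progress: the raw pooled
#'   descriptors carry a large all-positive common mode that otherwise
#'   dominates early gradients. Default `TRUE`; set `FALSE` when fine-tuning
#'   from a pretrained checkpoint.
#' @return An object of class `osfp_net` with fields `weights`, `config`,
#'   `control`, `history` (per-epoch data frame: epoch, lr, mean loss,
#'   running training accuracy, end-of-epoch accuracies), `best_weights`,
#'   `n_train`, and `call`. Methods: [print.osfp_net()], [summary.osfp_net()],
#'   [predict.osfp_net()], [plot.osfp_net()], [coef.osfp_net()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_subjects = 8, effect_size = 2,
#'                                       seed = 3))
#' fit <- osfp_net(cohort, model = osfp_config_tiny(),
#'                 control = train_control(epochs = 1, seed = 1))
#' predict(fit, cohort[1:2])
#' }
#' @export
osfp_net <- function(x, model = osfp_config(), control = train_control(),
                     validation = NULL, checkpoint = NULL,
                     standardize_init = TRUE) {
  stopifnot(inherits(model, "osfp_config"), inherits(control, "train_control"))
  if (!length(x)) stop_config("training cohort is empty")
  if (!is.null(validation)) {
    tr_ids <- unique(base_subject_id(vapply(x, `[[`, "", "subject_id")))
    va_ids <- unique(base_subject_id(vapply(validation, `[[`, "", "subject_id")))
    overlap <- intersect(tr_ids, va_ids)
    if (length(overlap)) {
      stop_config("protocol violation: subjects in both training and validation: %s",
                  paste(head(overlap, 5), collapse = ", "))
    }
  }
  weights <- init_osfp_weights(model, seed = control$seed,
                               checkpoint = checkpoint)
  if (standardize_init) {
    weights <- standardize_first_fc(weights, subject_batches(x))
  }
  velocity <- zero_like_weights(weights)
  val_batches <- if (!is.null(validation)) subject_batches(validation)
  history <- list()
  best <- list(acc = -Inf, weights = NULL, epoch = NA_integer_)
  stopped_early <- FALSE

  for (epoch in seq_len(control$epochs) - 1L) {
    lr <- lr_at_epoch(control, epoch)
    batches <- subject_batches(x, shuffle_seed = control$seed + 1000L * (epoch + 1L))
    losses <- numeric(length(batches))
    hits <- logical(length(batches))
    with_seed(control$seed + 7L + epoch, {
      for (i in seq_along(batches)) {
        b <- batches[[i]]
        fwd <- osfp_forward(weights, b$images, mode = "train")
        pr <- softmax(fwd$logits)
        losses[i] <- -log(max(pr[b$label + 1L], 1e-12))
        hits[i] <- (which.max(fwd$logits) - 1L) == b$label
        dlogits <- pr
        dlogits[b$label + 1L] <- dlogits[b$label + 1L] - 1
        grads <- clip_grads(osfp_backward(weights, fwd, dlogits),
                            control$clip_grad_norm)
        st <- sgd_step(weights, grads, velocity, lr, control$momentum)
        weights <- st$weights
        velocity <- st$velocity
      }
    })
    run_acc <- mean(hits)
    train_acc <- NA_real_
    val_acc <- NA_real_
    if (!is.null(val_batches)) {
      val_acc <- batch_accuracy(weights, val_batches)
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, weights = weights, epoch = epoch)
      }
    }
    if (!is.null(control$early_stop_acc) && run_acc >= control$early_stop_acc) {
      train_acc <- batch_accuracy(weights, subject_batches(x))
    }
    history[[length(history) + 1L]] <- data.frame(
      epoch = epoch, lr = lr, loss = mean(losses), running_acc = run_acc,
      train_acc = train_acc, val_acc = val_acc)
    if (control$verbose) {
      message(sprintf("epoch %2d  lr %.2g  loss %.4f  acc %.3f%s",
                      epoch, lr, mean(losses), run_acc,
                      if (is.na(val_acc)) "" else sprintf("  val %.3f", val_acc)))
    }
    if (!is.na(train_acc) && train_acc >= control$early_stop_acc) {
      stopped_early <- TRUE
      break
    }
  }

  history <- if (length(history)) do.call(rbind, history) else
    data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
               running_acc = numeric(), train_acc = numeric(),
               val_acc = numeric())
  structure(
    list(weights = weights, config = model, control = control,
         history = history,
         best_weights = best$weights, best_epoch = best$epoch,
         best_val_acc = if (is.finite(best$acc)) best$acc else NA_real_,
         stopped_early = stopped_early,
         n_train = length(x), call = match.call()),
    class = "osfp_net"
  )
}

#' Train one cross-validation fold
#'
#' Thin protocol wrapper around [osfp_net()]: checks that the training and
#' validation subject sets are disjoint, trains with the given control, and
#' returns the fitted model (whose history carries the per-epoch loss and
#' validation accuracy).
#'
#' @param model_cfg An [osfp_config()].
#' @param train_records,val_records Disjoint `plaque_cohort`s. Apply
#'   augmentation to `train_records` beforehand if wanted.
#' @param control A [train_control()].
#' @return An `osfp_net` fit.
#' @export
train_one_fold <- function(model_cfg, train_records, val_records,
                           control = train_control()) {
  osfp_net(train_records, model = model_cfg, control = control,
           validation = val_records)
}
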