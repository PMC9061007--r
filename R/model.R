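# Four-path model: per-path FE (backbone) + FD (object-specific pooling),
# descriptor concatenation in fixed path order (LT, LL, RT, RL), and a
# fully connected classification head with dropout before the last layer.

#' Four-path network configuration
#'
#' Paths 1 and 3 carry the transverse views (left, right) through SPP; paths
#' 2 and 4 carry the longitudinal views through MSP. With the default
#' backbone (`k = 512`) and default pooling the concatenated descriptor is
#' `2*14k + 2*6k = 40k = 20480` long. The head defaults to VGG16's
#' fully connected sizes (4096, 4096) with two output scores; dropout (drop
#' probability `dropout_drop`, i.e. Bernoulli retention `1 - dropout_drop`)
#' is applied before the last fully connected layer.
#'
#' @param backbone A [backbone_config()].
#' @param pooling_transverse A `"spp"` [pooling_spec()] for paths 1 and 3.
#' @param pooling_longitudinal A `"msp"` [pooling_spec()] for paths 2 and 4.
#' @param fc_sizes Hidden fully connected layer widths.
#' @param n_classes Number of output scores (2: asymptomatic, symptomatic).
#' @param dropout_drop Drop probability in \[0, 1\]; retention is
#'   `1 - dropout_drop`. Inverted dropout is used, so inference applies no
#'   rescaling.
#' @param tie_fe_weights If `TRUE` the four paths share one set of backbone
#'   weights; by default each path holds independent weights initialized
#'   identically.
#' @return An object of class `osfp_config`.
#' @export
osfp_config <- function(backbone = backbone_config(),
                        pooling_transverse = pooling_spec("spp"),
                        pooling_longitudinal = pooling_spec("msp"),
                        fc_sizes = c(4096L, 4096L),
                        n_classes = 2L,
                        dropout_drop = 0.5,
                        tie_fe_weights = FALSE) {
  stopifnot(inherits(backbone, "backbone_config"),
            inherits(pooling_transverse, "pooling_spec"),
            inherits(pooling_longitudinal, "pooling_spec"))
  if (pooling_transverse$kind != "spp" || pooling_longitudinal$kind != "msp") {
    stop_config("transverse paths use SPP and longitudinal paths use MSP")
  }
  if (dropout_drop < 0 || dropout_drop > 1) {
    stop_config("dropout_drop must lie in [0, 1]")
  }
  structure(
    list(backbone = backbone,
         pooling_transverse = pooling_transverse,
         pooling_longitudinal = pooling_longitudinal,
         fc_sizes = as.integer(fc_sizes),
         n_classes = as.integer(n_classes),
         dropout_drop = dropout_drop,
         tie_fe_weights = isTRUE(tie_fe_weights)),
    class = "osfp_config"
  )
}

#' Desk-scale model configuration
#'
#' The full architecture at 1/8 channel width (`k = 64`) with a (256, 256)
#' head: the same structure and contracts, small enough to train on a CPU in
#' minutes. Used throughout the package tests.
#'
#' @param ... Overrides forwarded to [osfp_config()].
#' @return An `osfp_config`.
#' @export
osfp_config_tiny <- function(...) {
  osfp_config(backbone = backbone_config(width_scale = 0.125),
              fc_sizes = c(256L, 256L), ...)
}

#' Length of the concatenated descriptor entering the classifier
#'
#' `k * (2 * SPP units + 2 * MSP units)`; 20480 for the default
#' configuration, 2560 for the desk-scale one.
#'
#' @param cfg An [osfp_config()].
#' @return Integer length.
#' @export
classifier_input_length <- function(cfg) {
  stopifnot(inherits(cfg, "osfp_config"))
  k <- backbone_k(cfg$backbone)
  k * (2L * pooling_units(cfg$pooling_transverse) +
         2L * pooling_units(cfg$pooling_longitudinal))
}

# Per-path pooling spec in path order LT, LL, RT, RL.
path_pooling <- function(cfg) {
  list(LT = cfg$pooling_transverse, LL = cfg$pooling_longitudinal,
       RT = cfg$pooling_transverse, RL = cfg$pooling_longitudinal)
}

#' Initialize the four-path network weights
#'
#' Builds the four backbones (independent copies initialized from the same
#' seed, or one shared backbone when `tie_fe_weights`) and the fully
#' connected head: hidden layers are He-initialized, the final scoring layer
#' starts at zero so the untrained network outputs the maximum-entropy
#' prediction (no random logit noise for early training to unlearn).
#'
#' @param cfg An [osfp_config()].
#' @param seed Integer seed for all weight initialization.
#' @param checkpoint Optional backbone checkpoint forwarded to
#'   [build_backbone()] (pretrained path).
#' @return An object of class `osfp_weights`.
#' @export
init_osfp_weights <- function(cfg, seed = 1L, checkpoint = NULL) {
  fe1 <- build_backbone(cfg$backbone, seed = seed, checkpoint = checkpoint)
  fes <- if (cfg$tie_fe_weights) {
    list(fe1)
  } else {
    lapply(1:4, function(p) fe1)  # same init per path, updated independently
  }
  in_len <- classifier_input_length(cfg)
  sizes <- c(in_len, cfg$fc_sizes, cfg$n_classes)
  n_fc <- length(sizes) - 1L
  fc <- with_seed(seed + 1L, lapply(seq_len(n_fc), function(i) {
    W <- if (i == n_fc) {
      matrix(0, sizes[i + 1], sizes[i])
    } else {
      matrix(rnorm(sizes[i + 1] * sizes[i], sd = sqrt(2 / sizes[i])),
             sizes[i + 1], sizes[i])
    }
    list(W = W, b = numeric(sizes[i + 1]))
  }))
  structure(list(cfg = cfg, fes = fes, fc = fc), class = "osfp_weights")
}

path_fe <- function(weights, p) {
  if (weights$cfg$tie_fe_weights) weights$fes[[1]] else weights$fes[[p]]
}

#' Apply dropout to a vector
#'
#' Training mode draws a Bernoulli retention mask `r_j ~ Bernoulli(p)` and
#' returns `r * y / p` (inverted dropout, so the expectation matches the
#' inference output and inference needs no rescaling). Inference mode is the
#' identity. `p` is the *retention* probability: `p = 1` keeps everything,
#' `p = 0` zeroes the vector.
#'
#' @param y Numeric vector.
#' @param p Retention probability in \[0, 1\].
#' @param mode `"train"` or `"inference"`.
#' @param seed Optional seed for the mask draw.
#' @return The masked vector; in training mode the mask is attached as
#'   attribute `"mask"`.
#' @export
apply_dropout <- function(y, p, mode = c("train", "inference"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    stop_config("retention probability p must lie in [0, 1] (got %s)",
                format(p))
  }
  if (mode == "inference") return(y)
  if (p == 0) {
    out <- y * 0
    attr(out, "mask") <- rep(0L, length(y))
    return(out)
  }
  mask <- with_seed(seed, rbinom(length(y), 1L, p))
  out <- y * mask / p
  attr(out, "mask") <- mask
  out
}

# Concatenated four-path descriptor for one subject (inference mode).
subject_descriptor <- function(weights, images) {
  pool_specs <- path_pooling(weights$cfg)
  unlist(lapply(1:4, function(p) {
    fmap <- backbone_forward(path_fe(weights, p), images[[p]])
    pool_forward(fmap, pool_specs[[p]])
  }), use.names = FALSE)
}

# Data-dependent initialization for training from scratch: estimate the
# per-feature mean and spread of the concatenated descriptor over the
# training subjects and fold the standardization into the first fully
# connected layer (W <- W / s, b <- b - W m/s). This only re-chooses the
# initial point -- the architecture and the set of reachable functions are
# unchanged -- but it removes the large all-positive common mode of
# max/average-pooled descriptors that otherwise dominates early gradients.
standardize_first_fc <- function(weights, batches) {
  D <- vapply(batches, function(b) subject_descriptor(weights, b$images),
              numeric(classifier_input_length(weights$cfg)))
  m <- rowMeans(D)
  s <- apply(D, 1, sd)
  # Floor the scale at the median spread: dominant features are damped to a
  # common scale but weak/dead features are never amplified (an unbounded
  # 1/s gain feeds back through the backbone and destabilizes batch-1 SGD).
  live <- is.finite(s) & s > 1e-8
  floor_s <- if (any(live)) stats::median(s[live]) else 1
  s[!live] <- 1
  s <- pmax(s, floor_s)
  W <- weights$fc[[1]]$W
  Ws <- sweep(W, 2, s, "/")
  weights$fc[[1]]$W <- Ws
  weights$fc[[1]]$b <- weights$fc[[1]]$b - as.numeric(Ws %*% m)
  weights
}

# Forward through the whole network for one subject quadruple.
# images: list of 4 matrices in path order (LT, LL, RT, RL), values in [0,1].
# Returns logits; with mode = "train", also all caches for the backward pass.
osfp_forward <- function(weights, images, mode = "inference") {
  cfg <- weights$cfg
  if (!is.list(images) || length(images) != 4) {
    stop_config("expected exactly 4 view images (LT, LL, RT, RL), got %d",
                length(images))
  }
  pool_specs <- path_pooling(cfg)
  train <- mode == "train"
  path_caches <- vector("list", 4)
  descs <- vector("list", 4)
  for (p in 1:4) {
    fwd <- backbone_forward(path_fe(weights, p), images[[p]],
                            mode = if (train) "train" else "inference")
    fmap <- if (train) fwd$out else fwd
    pooled <- pool_forward(fmap, pool_specs[[p]], cache = train)
    if (train) {
      descs[[p]] <- pooled$values
      path_caches[[p]] <- list(backbone = fwd$caches, pool = pooled)
    } else {
      descs[[p]] <- pooled
    }
  }
  x <- unlist(descs, use.names = FALSE)
  if (length(x) != classifier_input_length(cfg)) {
    stop_config("descriptor length %d does not match classifier input %d",
                length(x), classifier_input_length(cfg))
  }
  nfc <- length(weights$fc)
  fc_cache <- vector("list", nfc)
  retain <- 1 - cfg$dropout_drop
  for (i in seq_len(nfc)) {
    if (i == nfc && train) {
      x <- apply_dropout(x, retain, mode = "train")
      drop_mask <- attr(x, "mask")
      attributes(x) <- NULL
    } else {
      drop_mask <- NULL
    }
    layer <- weights$fc[[i]]
    z <- as.numeric(layer$W %*% x + layer$b)
    if (i < nfc) {
      y <- pmax(z, 0)
    } else {
      y <- z  # final scores: no activation
    }
    if (train) fc_cache[[i]] <- list(x = x, z = z, drop_mask = drop_mask)
    x <- y
  }
  if (train) {
    list(logits = x, path_caches = path_caches, fc_cache = fc_cache)
  } else {
    x
  }
}

# Backward pass: dlogits -> gradients for every parameter. Returns
# list(fes = per-path backbone grads (or one entry when tied), fc = head
# grads), shapes parallel to the weights.
osfp_backward <- function(weights, fwd, dlogits) {
  cfg <- weights$cfg
  nfc <- length(weights$fc)
  fc_grads <- vector("list", nfc)
  dy <- dlogits
  retain <- 1 - cfg$dropout_drop
  for (i in rev(seq_len(nfc))) {
    cache <- fc_cache_i <- fwd$fc_cache[[i]]
    if (i < nfc) dy <- dy * (cache$z > 0)
    fc_grads[[i]] <- list(dW = outer(dy, cache$x), db = dy)
    dx <- as.numeric(crossprod(weights$fc[[i]]$W, dy))
    if (!is.null(cache$drop_mask)) {
      dx <- if (retain > 0) dx * cache$drop_mask / retain else dx * 0
    }
    dy <- dx
  }
  # split descriptor gradient across the four paths
  pool_specs <- path_pooling(cfg)
  k <- backbone_k(cfg$backbone)
  lens <- vapply(pool_specs, function(s) k * pooling_units(s), 0L)
  offsets <- c(0L, cumsum(lens))
  fe_grads <- vector("list", if (cfg$tie_fe_weights) 1L else 4L)
  for (p in 1:4) {
    dvals <- dy[(offsets[p] + 1L):offsets[p + 1L]]
    pc <- fwd$path_caches[[p]]
    dfmap <- pool_backward(pc$pool, pool_specs[[p]], dvals)
    g <- backbone_backward(path_fe(weights, p), pc$backbone, dfmap)
    if (cfg$tie_fe_weights) {
      fe_grads[[1]] <- if (is.null(fe_grads[[1]])) g else {
        mapply(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
               fe_grads[[1]], g, SIMPLIFY = FALSE)
      }
    } else {
      fe_grads[[p]] <- g
    }
  }
  list(fes = fe_grads, fc = fc_grads)
}

#' Class scores for one subject quadruple
#'
#' Runs the four arbitrary-size views through their paths and the classifier
#' head in inference mode (deterministic; dropout inactive).
#'
#' @param weights An [init_osfp_weights()] result (or the `weights` field of
#'   a fitted [osfp_net()]).
#' @param images List of four numeric matrices in \[0, 1\], path order
#'   LT, LL, RT, RL.
#' @return Numeric vector of two scores (asymptomatic, symptomatic).
#' @export
osfp_scores <- function(weights, images) {
  stopifnot(inherits(weights, "osfp_weights"))
  osfp_forward(weights, images, mode = "inference")
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Save / load network weights
#'
#' Checkpoints serialize the full `osfp_weights` object (config echo plus
#' every parameter array) with `saveRDS`; path order and the conv weight
#' layout round-trip exactly.
#'
#' @param weights An `osfp_weights` object.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `osfp_weights`.
#' @export
save_checkpoint <- function(weights, path) {
  stopifnot(inherits(weights, "osfp_weights"))
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  w <- readRDS(path)
  if (!inherits(w, "osfp_weights")) stop_config("%s is not a checkpoint", path)
  w
}
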