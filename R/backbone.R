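# VGG16-style feature-extraction subnetwork (FE): five blocks of 3x3
# stride-1 pad-1 convolutions with ReLU, a 2x2 stride-2 max pool after every
# block except (by default) the last, so an HxW input yields k feature maps
# of roughly H/16 x W/16 with no resizing of the input.

#' Minimum accepted input side length
#'
#' 48 px per side guarantees at least a 3x3 feature map after the four
#' stride-2 pools of the default backbone (48 -> 24 -> 12 -> 6 -> 3), which
#' the 3x3 pyramid level of the downstream pooling requires.
#'
#' @return Integer scalar, 48.
#' @export
osfp_min_input <- function() 48L

#' Backbone (feature-extraction subnetwork) configuration
#'
#' The default mirrors the convolutional stage of VGG16: five blocks of
#' (2, 2, 3, 3, 3) convolutions with (64, 128, 256, 512, 512) channels, all
#' 3x3 with stride and padding 1 and ReLU activations, each block followed by
#' a 2x2 stride-2 max pool except the last (`pool_after_last_block = FALSE`),
#' so arbitrary-size inputs produce arbitrary-size feature maps at 1/16
#' resolution with `k = 512` channels.
#'
#' @param n_blocks Number of conv blocks.
#' @param convs_per_block Integer vector, convolutions per block.
#' @param channels Integer vector, output channels per block (before
#'   `width_scale`).
#' @param pool_after_last_block Keep the pool after the final block (the
#'   four-path architecture omits it so the final map stays at 1/16).
#' @param pretrained If `TRUE`, weights must be supplied via the `checkpoint`
#'   argument of [build_backbone()] (an ILSVRC-trained VGG16 convolutional
#'   stage); incompatible with `width_scale != 1`.
#' @param width_scale Multiplier on all channel counts; `0.125` gives the
#'   desk-scale variant (`k = 64`) used throughout the tests.
#' @param in_channels Input channels: 1 for grayscale training from scratch
#'   (default), 3 when adapting pretrained RGB weights by replicating the
#'   grayscale plane.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(n_blocks = 5L,
                            convs_per_block = c(2L, 2L, 3L, 3L, 3L),
                            channels = c(64L, 128L, 256L, 512L, 512L),
                            pool_after_last_block = FALSE,
                            pretrained = FALSE,
                            width_scale = 1,
                            in_channels = if (pretrained) 3L else 1L) {
  if (length(convs_per_block) != n_blocks || length(channels) != n_blocks) {
    stop_config("convs_per_block and channels must each have n_blocks = %d entries",
                n_blocks)
  }
  if (width_scale <= 0) stop_config("width_scale must be positive")
  if (pretrained && width_scale != 1) {
    stop_config("pretrained weights require width_scale = 1 (got %g): channel shapes would not match",
                width_scale)
  }
  ch <- pmax(1L, as.integer(round(channels * width_scale)))
  structure(
    list(n_blocks = as.integer(n_blocks),
         convs_per_block = as.integer(convs_per_block),
         channels = ch,
         pool_after_last_block = isTRUE(pool_after_last_block),
         pretrained = isTRUE(pretrained),
         width_scale = width_scale,
         in_channels = as.integer(in_channels)),
    class = "backbone_config"
  )
}

#' Feature-map channel count of a backbone
#' @param cfg A [backbone_config()].
#' @return Integer `k`, the channel count of the final feature maps.
#' @export
backbone_k <- function(cfg) cfg$channels[cfg$n_blocks]

n_pools <- function(cfg) {
  cfg$n_blocks - 1L + as.integer(cfg$pool_after_last_block)
}

#' Spatial size of the feature map for a given input size
#'
#' Applies the floor-division chain of the stride-2 pools: each pool maps an
#' extent `e` to `floor(e / 2)`.
#'
#' @param cfg A [backbone_config()].
#' @param height,width Input pixel dimensions.
#' @return Integer `c(h, w)` of the final feature map.
#' @export
feature_map_size <- function(cfg, height, width) {
  e <- c(as.integer(height), as.integer(width))
  for (i in seq_len(n_pools(cfg))) e <- e %/% 2L
  e
}

# Per-conv-layer shapes: list of (c_in, c_out, block)
backbone_layer_dims <- function(cfg) {
  dims <- list()
  c_in <- cfg$in_channels
  for (b in seq_len(cfg$n_blocks)) {
    for (l in seq_len(cfg$convs_per_block[b])) {
      dims[[length(dims) + 1L]] <- list(c_in = c_in, c_out = cfg$channels[b],
                                        block = b)
      c_in <- cfg$channels[b]
    }
  }
  dims
}

#' Trainable parameter count of a backbone
#' @param cfg A [backbone_config()].
#' @return Total number of weights and biases across all conv layers.
#' @export
backbone_n_params <- function(cfg) {
  sum(vapply(backbone_layer_dims(cfg),
             function(d) 9 * d$c_in * d$c_out + d$c_out, 0))
}

#' Build (initialize) a feature-extraction subnetwork
#'
#' Weights use seeded He-normal initialization (`sd = sqrt(2 / fan_in)`) with
#' zero biases, the standard choice for ReLU stacks. With
#' `cfg$pretrained = TRUE` a checkpoint file (as written by
#' [save_checkpoint()], holding an ILSVRC-trained VGG16 convolutional stage)
#' must be supplied; no checkpoint ships with the package.
#'
#' @param cfg A [backbone_config()].
#' @param seed Integer seed for the random initialization.
#' @param checkpoint Optional path to a saved backbone checkpoint.
#' @return An object of class `osfp_backbone`: the config plus a list of
#'   per-layer weight matrices (`W`: `c_out x 9*c_in`) and bias vectors.
#' @export
build_backbone <- function(cfg = backbone_config(), seed = 1L,
                           checkpoint = NULL) {
  stopifnot(inherits(cfg, "backbone_config"))
  dims <- backbone_layer_dims(cfg)
  if (cfg$pretrained) {
    if (is.null(checkpoint)) {
      stop_config(paste0("pretrained = TRUE requires `checkpoint`, a file of ",
                         "ILSVRC-trained VGG16 convolutional weights; none is ",
                         "bundled with the package"))
    }
    layers <- readRDS(checkpoint)
    if (length(layers) != length(dims)) {
      stop_config("checkpoint has %d conv layers, config expects %d",
                  length(layers), length(dims))
    }
    for (i in seq_along(dims)) {
      d <- dims[[i]]
      if (!all(dim(layers[[i]]$W) == c(d$c_out, 9L * d$c_in))) {
        stop_config("checkpoint layer %d has shape %s, expected %dx%d", i,
                    paste(dim(layers[[i]]$W), collapse = "x"),
                    d$c_out, 9L * d$c_in)
      }
    }
  } else {
    layers <- with_seed(seed, lapply(dims, function(d) {
      fan_in <- 9 * d$c_in
      list(W = matrix(rnorm(d$c_out * 9L * d$c_in, sd = sqrt(2 / fan_in)),
                      d$c_out, 9L * d$c_in),
           b = numeric(d$c_out))
    }))
  }
  structure(list(cfg = cfg, layers = layers), class = "osfp_backbone")
}

# image -> (H, W, C) array, replicating grayscale when in_channels = 3
as_input_array <- function(image, in_channels) {
  if (is.matrix(image)) {
    image <- array(rep(image, in_channels),
                   dim = c(nrow(image), ncol(image), in_channels))
  }
  image
}

# Forward pass through the FE. mode = "train" additionally returns the
# per-layer caches needed by backbone_backward().
backbone_forward <- function(fe, image, mode = "inference") {
  cfg <- fe$cfg
  m <- osfp_min_input()
  if (nrow(image) < m || ncol(image) < m) {
    stop_config("input is %dx%d px; the backbone requires at least %dx%d",
                nrow(image), ncol(image), m, m)
  }
  x <- as_input_array(image, cfg$in_channels)
  caches <- if (mode == "train") list() else NULL
  li <- 0L
  for (b in seq_len(cfg$n_blocks)) {
    for (l in seq_len(cfg$convs_per_block[b])) {
      li <- li + 1L
      layer <- fe$layers[[li]]
      z <- cpp_conv3x3_fwd(x, layer$W, layer$b)
      if (!is.null(caches)) {
        caches[[length(caches) + 1L]] <-
          list(kind = "conv", layer = li, x = x, relu_mask = z > 0)
      }
      y <- z
      y[y < 0] <- 0
      x <- y
    }
    if (b < cfg$n_blocks || cfg$pool_after_last_block) {
      mp <- cpp_maxpool2_fwd(x)
      if (!is.null(caches)) {
        caches[[length(caches) + 1L]] <-
          list(kind = "pool", idx = mp$idx, H = nrow(x), W = ncol(x))
      }
      x <- mp$out
    }
  }
  if (is.null(caches)) x else list(out = x, caches = caches)
}

# Backward through the FE given the cached forward. Returns dgrads: a list
# parallel to fe$layers of (dW, db). The gradient w.r.t. the input image is
# not needed (images are data) and is discarded after the first layer.
backbone_backward <- function(fe, caches, dout) {
  grads <- vector("list", length(fe$layers))
  dy <- dout
  for (ci in rev(seq_along(caches))) {
    cache <- caches[[ci]]
    if (cache$kind == "pool") {
      dy <- cpp_maxpool2_bwd(cache$idx, cache$H, cache$W, dy)
    } else {
      layer <- fe$layers[[cache$layer]]
      dy[!cache$relu_mask] <- 0
      g <- cpp_conv3x3_bwd(cache$x, layer$W, dy,
                           need_dx = cache$layer > 1L)
      grads[[cache$layer]] <- list(dW = g$dw, db = as.numeric(g$db))
      dy <- g$dx
    }
  }
  grads
}

#' Extract feature maps from one image
#'
#' Runs the sliding-window convolutional stage over an image of arbitrary
#' size (at least [osfp_min_input()] per side) without any resizing.
#'
#' @param fe An [build_backbone()] result.
#' @param image Numeric matrix in \[0, 1\] (or an `(H, W, C)` array matching
#'   the configured input channels).
#' @return `(h, w, k)` array of feature maps, with `h, w` following the
#'   floor-division chain of [feature_map_size()].
#' @export
extract_features <- function(fe, image) {
  stopifnot(inherits(fe, "osfp_backbone"))
  backbone_forward(fe, image, mode = "inference")
}
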