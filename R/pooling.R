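# Object-specific feature downsampling (FD): spatial pyramid pooling (SPP)
# for near-square transverse-section feature maps and multilevel strip
# pooling (MSP) for elongated longitudinal-section maps. Both reduce a
# k x h x w feature map of any spatial size to a fixed-length descriptor.

#' Pooling specification for a feature-downsampling subnetwork
#'
#' A multilevel adaptive pooling layout. Each level is a grid of
#' `a_n x b_n` bins laid adaptively over the feature map:
#' * SPP levels are square grids (`b_n = a_n`); the default 3-level pyramid
#'   `1x1, 2x2, 3x3` gives 14 bins per channel.
#' * MSP levels are strips (`b_n = 1`): `a_n` divisions along the map height,
#'   each spanning the full width, so every strip aggregates long-range
#'   horizontal context; the default `1x1, 2x1, 3x1` gives 6 strips per
#'   channel.
#'
#' The per-channel descriptor length is `sum(a_n * b_n)`, independent of the
#' feature-map size. Default reduction operators: max for SPP, average for
#' MSP (both configurable).
#'
#' @param kind `"spp"` or `"msp"`.
#' @param levels List of `c(a_n, b_n)` grid shapes; `NULL` gives the default
#'   3-level layout for the kind.
#' @param operator `"max"` or `"average"`; `NULL` gives the kind's default.
#' @return An object of class `pooling_spec`.
#' @examples
#' pooling_units(pooling_spec("spp"))  # 14
#' pooling_units(pooling_spec("msp"))  # 6
#' @export
pooling_spec <- function(kind = c("spp", "msp"), levels = NULL,
                         operator = NULL) {
  kind <- match.arg(kind)
  if (is.null(levels)) {
    levels <- if (kind == "spp") {
      list(c(1L, 1L), c(2L, 2L), c(3L, 3L))
    } else {
      list(c(1L, 1L), c(2L, 1L), c(3L, 1L))
    }
  }
  levels <- lapply(levels, function(l) {
    l <- as.integer(l)
    if (length(l) != 2 || any(l < 1)) {
      stop_config("each level must be a positive c(a, b) pair")
    }
    if (kind == "spp" && l[1] != l[2]) {
      stop_config("SPP levels must be square grids (got %dx%d)", l[1], l[2])
    }
    if (kind == "msp" && l[2] != 1L) {
      stop_config("MSP levels must be strips a x 1 (got %dx%d)", l[1], l[2])
    }
    l
  })
  operator <- operator %||% if (kind == "spp") "max" else "average"
  operator <- match.arg(operator, c("max", "average"))
  structure(list(kind = kind, levels = levels, operator = operator),
            class = "pooling_spec")
}

#' @export
print.pooling_spec <- function(x, ...) {
  lv <- vapply(x$levels, function(l) sprintf("%dx%d", l[1], l[2]), "")
  cat(sprintf("%s pooling (%s): levels %s; %d units per channel\n",
              toupper(x$kind), x$operator, paste(lv, collapse = ", "),
              pooling_units(x)))
  invisible(x)
}

#' Total pooled units per channel
#' @param spec A [pooling_spec()].
#' @return `sum(a_n * b_n)` over the levels.
#' @export
pooling_units <- function(spec) {
  stopifnot(inherits(spec, "pooling_spec"))
  sum(vapply(spec$levels, function(l) l[1] * l[2], 0L))
}

#' Adaptive bin boundaries along one axis
#'
#' Splits an extent of `extent` cells into `n_bins` adaptive bins using the
#' floor-start / ceil-end convention: bin `i` (0-based) covers the 0-based
#' half-open index range `[floor(i * extent / n), ceil((i + 1) * extent / n))`.
#' Bins jointly cover every cell; adjacent bins may overlap by a cell when
#' `extent` is not a multiple of `n_bins`.
#'
#' @param extent Positive integer axis length.
#' @param n_bins Number of bins, `1 <= n_bins <= extent`.
#' @return Integer matrix with columns `start`, `end` (0-based, half-open).
#' @examples
#' adaptive_bin_edges(5, 3)  # [0,2) [1,4) [3,5)
#' @export
adaptive_bin_edges <- function(extent, n_bins) {
  if (!is_count(extent) || !is_count(n_bins) || n_bins < 1) {
    stop_config("extent and n_bins must be positive integers")
  }
  if (n_bins > extent) {
    stop_config("cannot split extent %d into %d bins: need extent >= n_bins",
                extent, n_bins)
  }
  i <- seq_len(n_bins) - 1
  cbind(start = floor(i * extent / n_bins),
        end = ceiling((i + 1) * extent / n_bins))
}

# Forward adaptive pooling. fmap: (h, w, k) array. Returns the descriptor
# and, when cache = TRUE, the bin geometry plus argmax positions needed for
# the backward pass.
# Descriptor layout: levels in listed order; within a level channels are
# contiguous, and within a channel units run in row-major bin order.
pool_forward <- function(fmap, spec, cache = FALSE) {
  h <- dim(fmap)[1]; w <- dim(fmap)[2]; k <- dim(fmap)[3]
  amax <- max(vapply(spec$levels, `[`, 0L, 1))
  bmax <- max(vapply(spec$levels, `[`, 0L, 2))
  if (h < amax || w < bmax) {
    stop_config("feature map %dx%d is smaller than the finest %dx%d grid; inputs must give a map of at least %dx%d",
                h, w, amax, bmax, amax, bmax)
  }
  values <- numeric(k * pooling_units(spec))
  pos <- if (cache) vector("list", length(values)) else NULL
  chs <- seq_len(k)
  off <- 0L
  for (lev in spec$levels) {
    a <- lev[1]; b <- lev[2]
    re <- adaptive_bin_edges(h, a)
    ce <- adaptive_bin_edges(w, b)
    ab <- a * b
    for (r in seq_len(a)) {
      rows <- (re[r, "start"] + 1L):re[r, "end"]
      for (cl in seq_len(b)) {
        cols <- (ce[cl, "start"] + 1L):ce[cl, "end"]
        u <- (r - 1L) * b + cl
        vi <- off + (chs - 1L) * ab + u          # one slot per channel
        sub <- fmap[rows, cols, , drop = FALSE]
        nb <- length(rows) * length(cols)
        m <- matrix(sub, nb, k)
        if (spec$operator == "max") {
          am <- max.col(t(m), ties.method = "first")  # argmax per channel
          values[vi] <- m[cbind(am, chs)]
          if (cache) {
            ri <- rows[(am - 1L) %% length(rows) + 1L]
            ci <- cols[(am - 1L) %/% length(rows) + 1L]
            for (ch in chs) pos[[vi[ch]]] <- c(ri[ch], ci[ch], ch)
          }
        } else {
          values[vi] <- colMeans(m)
          if (cache) {
            for (ch in chs) pos[[vi[ch]]] <- list(rows = rows, cols = cols,
                                                  ch = ch)
          }
        }
      }
    }
    off <- off + k * ab
  }
  if (cache) list(values = values, pos = pos, dim = dim(fmap)) else values
}

# Backward of pool_forward: route each descriptor gradient back to the cell
# (max) or spread it uniformly over the bin (average).
pool_backward <- function(cache, spec, dvalues) {
  dfmap <- array(0, dim = cache$dim)
  if (spec$operator == "max") {
    for (vi in seq_along(dvalues)) {
      p <- cache$pos[[vi]]
      dfmap[p[1], p[2], p[3]] <- dfmap[p[1], p[2], p[3]] + dvalues[vi]
    }
  } else {
    for (vi in seq_along(dvalues)) {
      p <- cache$pos[[vi]]
      nb <- length(p$rows) * length(p$cols)
      dfmap[p$rows, p$cols, p$ch] <-
        dfmap[p$rows, p$cols, p$ch] + dvalues[vi] / nb
    }
  }
  dfmap
}

#' Pool a feature map to a fixed-length descriptor
#'
#' Applies every level of the spec to the map: the map is partitioned into an
#' adaptive `a_n x b_n` grid per level ([adaptive_bin_edges()] convention),
#' each bin is reduced by the operator separately per channel, and level
#' outputs are concatenated (levels in order; channels contiguous within a
#' level; bins row-major within a channel). The result length
#' `k * pooling_units(spec)` does not depend on the map's spatial size.
#'
#' @param fmap `(h, w, k)` feature-map array, e.g. from [extract_features()].
#' @param spec A [pooling_spec()].
#' @return Numeric descriptor of length `k * pooling_units(spec)`.
#' @export
pool_features <- function(fmap, spec) {
  stopifnot(inherits(spec, "pooling_spec"))
  if (length(dim(fmap)) != 3) stop_config("fmap must be an (h, w, k) array")
  pool_forward(fmap, spec, cache = FALSE)
}
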