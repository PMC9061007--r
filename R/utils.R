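# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic package components route their draws through this so that a
# given seed fully determines the output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

# integer uniform on [lo, hi] inclusive
runif_int <- function(n, lo, hi) {
  lo + floor(runif(n) * (hi - lo + 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

VIEW_KEYS <- c("LT", "LL", "RT", "RL")
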