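# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small default-geometry cohort.
small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(cohort_spec(n_subjects = 10, seed = 7)))
}

# Cohort whose smallest side is 60 px so every 0.8-scaled variant stays
# at or above the 48 px minimum input size.
augmentable_cohort <- function(n = 5, seed = 2) {
  generate_cohort(cohort_spec(
    n_subjects = n, seed = seed,
    transverse_size_range = c(60L, 160L),
    longitudinal_height_range = c(60L, 96L)))
}

# Desk-scale end-to-end cohort: same structure and class model, smaller ROI
# ranges so a full training run fits in CPU-minutes.
desk_cohort <- function(effect_size, seed, n = 40) {
  generate_cohort(cohort_spec(
    n_subjects = n, effect_size = effect_size, seed = seed,
    transverse_size_range = c(48L, 96L),
    longitudinal_height_range = c(48L, 64L),
    longitudinal_aspect_range = c(2.5, 3.5)))
}

# Narrow backbone: full depth, few channels, cheap forward/backward.
micro_backbone <- function() {
  backbone_config(convs_per_block = c(1L, 1L, 1L, 1L, 1L),
                  channels = c(2L, 3L, 3L, 4L, 4L))
}

micro_config <- function(...) {
  osfp_config(backbone = micro_backbone(), fc_sizes = c(8L, 8L), ...)
}

random_image <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Independent brute-force adaptive pooling: enumerates every bin's cells
# directly from the floor/ceil boundary definition.
brute_force_pool <- function(fmap, levels, operator) {
  h <- dim(fmap)[1]; w <- dim(fmap)[2]; k <- dim(fmap)[3]
  out <- numeric(0)
  for (lev in levels) {
    a <- lev[1]; b <- lev[2]
    for (ch in seq_len(k)) {
      for (r in seq_len(a)) {
        r0 <- floor((r - 1) * h / a) + 1
        r1 <- ceiling(r * h / a)
        for (cl in seq_len(b)) {
          c0 <- floor((cl - 1) * w / b) + 1
          c1 <- ceiling(cl * w / b)
          cells <- as.numeric(fmap[r0:r1, c0:c1, ch])
          out <- c(out, if (operator == "max") max(cells) else mean(cells))
        }
      }
    }
  }
  out
}

# Pair-ordering (Mann-Whitney) AUC: fraction of (positive, negative) pairs
# ranked correctly, ties counted half.
pair_order_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
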