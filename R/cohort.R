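# Synthetic carotid-plaque cohort generator.
#
# Emulates the structure of a bilateral two-section plaque ultrasound study:
# each subject contributes four grayscale ROIs (left/right artery, transverse/
# longitudinal section) of arbitrary pixel size, plus a binary outcome label
# (1 = symptomatic, 0 = asymptomatic). Texture is multiplicative Rayleigh
# speckle over a smooth echogenicity background; the symptomatic class is
# rendered hypoechoic (lower mean) and more heterogeneous (higher background
# contrast), scaled by `effect_size`.

#' Specification of a synthetic plaque cohort
#'
#' Describes the geometry and class structure of a synthetic cohort of
#' subjects, each imaged as four grayscale plaque ROIs: left and right
#' carotid artery in transverse (near-square) and longitudinal (elongated)
#' section.
#'
#' The intensity model is classical fully developed B-mode speckle:
#' a Gaussian-smoothed random echogenicity background multiplied by
#' Rayleigh-distributed noise with unit mean. The symptomatic class differs
#' from the asymptomatic class by a mean-echogenicity deficit and a background
#' contrast (heterogeneity) excess, both proportional to `effect_size`;
#' `effect_size = 0` makes the two classes statistically identical.
#'
#' @param n_subjects Number of subjects (at least 5, so a 5-fold patient-level
#'   partition exists).
#' @param symptomatic_fraction Fraction of subjects labelled symptomatic,
#'   in (0, 1). The default 117/333 mirrors a typical symptomatic:asymptomatic
#'   imbalance in hospital plaque cohorts.
#' @param transverse_size_range Integer `c(min, max)` of the transverse ROI
#'   side length in pixels. Both sides are drawn from this range subject to a
#'   near-square aspect ratio (width/height in \[0.75, 1.33\]).
#' @param longitudinal_height_range Integer `c(min, max)` of the longitudinal
#'   ROI height in pixels.
#' @param longitudinal_aspect_range Numeric `c(min, max)` width/height ratio
#'   of longitudinal ROIs; the minimum must be at least 2 (long-strip shape).
#' @param effect_size Nonnegative scalar scaling the class separation
#'   (mean shift and heterogeneity ratio). 0 = no class signal; 1 = clearly
#'   separable per-image mean intensities.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [write_cohort()]
#' @export
cohort_spec <- function(n_subjects = 333L,
                        symptomatic_fraction = 117 / 333,
                        transverse_size_range = c(48L, 160L),
                        longitudinal_height_range = c(48L, 96L),
                        longitudinal_aspect_range = c(2.5, 5),
                        effect_size = 1,
                        seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 5) {
    stop_config("n_subjects must be an integer >= 5 (got %s)",
                format(n_subjects))
  }
  if (!is.numeric(symptomatic_fraction) ||
      symptomatic_fraction <= 0 || symptomatic_fraction >= 1) {
    stop_config("symptomatic_fraction must lie in (0, 1)")
  }
  check_range <- function(r, name, lo_floor) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop_config("%s must be c(min, max) with min <= max", name)
    }
    if (r[1] < lo_floor) {
      stop_config("%s minimum %s is below the smallest accepted input size %s",
                  name, format(r[1]), format(lo_floor))
    }
  }
  check_range(transverse_size_range, "transverse_size_range", osfp_min_input())
  check_range(longitudinal_height_range, "longitudinal_height_range",
              osfp_min_input())
  if (length(longitudinal_aspect_range) != 2 ||
      longitudinal_aspect_range[1] < 2 ||
      longitudinal_aspect_range[1] > longitudinal_aspect_range[2]) {
    stop_config("longitudinal_aspect_range must be c(min, max) with min >= 2")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size < 0) {
    stop_config("effect_size must be a nonnegative scalar")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         symptomatic_fraction = symptomatic_fraction,
         transverse_size_range = as.integer(transverse_size_range),
         longitudinal_height_range = as.integer(longitudinal_height_range),
         longitudinal_aspect_range = as.numeric(longitudinal_aspect_range),
         effect_size = effect_size,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic plaque cohort spec\n")
  cat(sprintf("  subjects: %d (symptomatic fraction %.3f)\n",
              x$n_subjects, x$symptomatic_fraction))
  cat(sprintf("  transverse sides: %d-%d px; longitudinal: height %d-%d px, aspect %.2f-%.2f\n",
              x$transverse_size_range[1], x$transverse_size_range[2],
              x$longitudinal_height_range[1], x$longitudinal_height_range[2],
              x$longitudinal_aspect_range[1], x$longitudinal_aspect_range[2]))
  cat(sprintf("  effect size: %g; seed: %d\n", x$effect_size, x$seed))
  invisible(x)
}

#' Construct a single plaque ROI image record
#'
#' @param pixels Integer matrix of 8-bit intensities (0-255), rows = image
#'   height.
#' @param side `"L"` or `"R"`.
#' @param section `"transverse"` or `"longitudinal"`.
#' @return An object of class `plaque_image` with fields `pixels`, `side`,
#'   `section`, `height`, `width`.
#' @export
plaque_image <- function(pixels, side, section) {
  side <- match.arg(side, c("L", "R"))
  section <- match.arg(section, c("transverse", "longitudinal"))
  if (!is.matrix(pixels)) stop_config("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  img <- structure(
    list(pixels = pixels, side = side, section = section,
         height = nrow(pixels), width = ncol(pixels)),
    class = "plaque_image"
  )
  validate_plaque_image(img)
  img
}

# Aspect-ratio bounds carry a 1% multiplicative slack so that integer
# rounding of scaled variants cannot invalidate a legal image.
validate_plaque_image <- function(img, what = "image") {
  h <- img$height
  w <- img$width
  m <- osfp_min_input()
  if (h < m || w < m) {
    stop_config("%s is %dx%d px but the network requires at least %dx%d",
                what, h, w, m, m)
  }
  r <- w / h
  if (img$section == "transverse") {
    if (r < 0.75 / 1.01 || r > 1.33 * 1.01) {
      stop_config("transverse %s aspect ratio %.3f outside [0.75, 1.33]",
                  what, r)
    }
  } else if (r < 2 / 1.01) {
    stop_config("longitudinal %s aspect ratio %.3f below 2", what, r)
  }
  if (any(img$pixels < 0L | img$pixels > 255L)) {
    stop_config("%s intensities outside 8-bit range", what)
  }
  invisible(img)
}

#' Construct a subject record (four views plus label)
#'
#' @param subject_id Character scalar.
#' @param label 0 (asymptomatic) or 1 (symptomatic).
#' @param images Named list with exactly the four entries `LT`, `LL`, `RT`,
#'   `RL`, each a [plaque_image()].
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, label, images) {
  if (!setequal(names(images), VIEW_KEYS) || length(images) != 4) {
    stop_config("subject %s: images must be exactly the four views %s",
                subject_id, paste(VIEW_KEYS, collapse = ", "))
  }
  if (!label %in% c(0L, 1L)) {
    stop_config("subject %s: label must be 0 or 1 (got %s)",
                subject_id, format(label))
  }
  images <- images[VIEW_KEYS]
  for (k in VIEW_KEYS) {
    img <- images[[k]]
    want_side <- substr(k, 1, 1)
    want_sec <- if (substr(k, 2, 2) == "T") "transverse" else "longitudinal"
    if (img$side != want_side || img$section != want_sec) {
      stop_config("subject %s: view %s has side/section %s/%s",
                  subject_id, k, img$side, img$section)
    }
    validate_plaque_image(img, what = sprintf("subject %s view %s", subject_id, k))
  }
  structure(
    list(subject_id = as.character(subject_id), label = as.integer(label),
         images = images),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  dims <- vapply(x$images, function(i) sprintf("%dx%d", i$height, i$width), "")
  cat(sprintf("Subject %s (label %d): %s\n", x$subject_id, x$label,
              paste(sprintf("%s %s", names(dims), dims), collapse = ", ")))
  invisible(x)
}

# Smooth unit-variance random field: white noise blurred with a Gaussian
# kernel, then restandardized. sigma is in pixels.
smooth_field <- function(h, w, sigma = 6) {
  z <- matrix(rnorm(h * w), h, w)
  z <- EBImage::gblur(z, sigma = sigma, radius = 2 * ceiling(2 * sigma) + 1)
  s <- sd(as.numeric(z))
  if (s < .Machine$double.eps) return(matrix(0, h, w))
  (z - mean(z)) / s
}

# Rayleigh multiplicative speckle with unit mean: sigma = sqrt(2/pi).
rayleigh_speckle <- function(h, w) {
  matrix(sqrt(2 / pi) * sqrt(-2 * log(runif(h * w))), h, w)
}

# Class intensity model. Baseline echogenicity 0.60; symptomatic plaques are
# hypoechoic by 0.08*effect_size and 75%*effect_size more heterogeneous.
speckle_image <- function(h, w, symptomatic, effect_size) {
  mu <- 0.60 - if (symptomatic) 0.08 * effect_size else 0
  contrast <- 0.06 * (1 + if (symptomatic) 0.75 * effect_size else 0)
  base <- mu + contrast * smooth_field(h, w)
  img <- pmin(pmax(base * rayleigh_speckle(h, w), 0), 1)
  matrix(as.integer(round(255 * img)), h, w)
}

draw_transverse_dims <- function(rng) {
  h <- runif_int(1, rng[1], rng[2])
  wlo <- max(rng[1], ceiling(0.76 * h))
  whi <- min(rng[2], floor(1.32 * h))
  c(h, runif_int(1, wlo, whi))
}

draw_longitudinal_dims <- function(hr, ar) {
  h <- runif_int(1, hr[1], hr[2])
  aspect <- runif(1, ar[1], ar[2])
  c(h, as.integer(round(aspect * h)))
}

#' Generate a synthetic plaque cohort
#'
#' Draws a labelled cohort of subjects, each with four speckle-textured
#' grayscale ROIs of random size: near-square transverse views and elongated
#' longitudinal views for the left and right carotid artery. The output is a
#' deterministic function of the spec (including its seed); class counts
#' follow `round(n_subjects * symptomatic_fraction)`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [subject_record()]s with class `plaque_cohort`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 6, seed = 1))
#' length(cohort)        # 6 subjects
#' cohort[[1]]
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  n_pos <- as.integer(round(n * spec$symptomatic_fraction))
  with_seed(spec$seed, {
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    records <- vector("list", n)
    for (i in seq_len(n)) {
      sid <- sprintf("S%04d", i)
      sym <- labels[i] == 1L
      imgs <- list()
      for (k in VIEW_KEYS) {
        sec <- if (substr(k, 2, 2) == "T") "transverse" else "longitudinal"
        d <- if (sec == "transverse") {
          draw_transverse_dims(spec$transverse_size_range)
        } else {
          draw_longitudinal_dims(spec$longitudinal_height_range,
                                 spec$longitudinal_aspect_range)
        }
        imgs[[k]] <- plaque_image(
          speckle_image(d[1], d[2], sym, spec$effect_size),
          side = substr(k, 1, 1), section = sec
        )
      }
      records[[i]] <- subject_record(sid, labels[i], imgs)
    }
    structure(records, class = c("plaque_cohort", "list"))
  })
}

#' @export
print.plaque_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, 0L, "label")
  cat(sprintf("Plaque cohort: %d subjects (%d symptomatic, %d asymptomatic), %d images\n",
              length(x), sum(labs == 1L), sum(labs == 0L), 4L * length(x)))
  invisible(x)
}

#' Total number of images in a cohort
#' @param records A `plaque_cohort` or list of [subject_record()]s.
#' @return Integer count (four per subject).
#' @export
n_images <- function(records) {
  sum(vapply(records, function(r) length(r$images), 0L))
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' One 8-bit grayscale PNG per view, named `<subject_id>_<view>.png`, and a
#' manifest `manifest.csv` with columns `subject_id`, `label`, `img_LT`,
#' `img_LL`, `img_RT`, `img_RL` holding paths relative to the manifest
#' location. The on-disk form round-trips exactly through [load_manifest()].
#'
#' @param records A `plaque_cohort` or list of [subject_record()]s.
#' @param out_dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_config("cannot create directory %s", out_dir)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    paths <- character(4)
    names(paths) <- VIEW_KEYS
    for (k in VIEW_KEYS) {
      f <- sprintf("%s_%s.png", rec$subject_id, k)
      png::writePNG(rec$images[[k]]$pixels / 255, file.path(out_dir, f))
      paths[k] <- f
    }
    rows[[i]] <- data.frame(subject_id = rec$subject_id, label = rec$label,
                            img_LT = paths["LT"], img_LL = paths["LL"],
                            img_RT = paths["RT"], img_RL = paths["RL"],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
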