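# Data pipeline: manifest loading, subject-consistent augmentation, and
# batch-size-1 serving of per-subject image quadruples.

#' Load a plaque cohort from a CSV manifest
#'
#' Reads the manifest written by [write_cohort()] (columns `subject_id`,
#' `label`, `img_LT`, `img_LL`, `img_RT`, `img_RL`; image paths relative to
#' the manifest) and validates every record: four views per subject, binary
#' labels, minimum input size, and section-specific aspect ratios.
#'
#' @param path Path to the manifest CSV.
#' @return A `plaque_cohort` (list of [subject_record()]s).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop_config("manifest not found: %s", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", paste0("img_", VIEW_KEYS))
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop_config("manifest %s lacks columns: %s", path,
                paste(missing_cols, collapse = ", "))
  }
  base <- dirname(path)
  records <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sid <- man$subject_id[i]
    if (!man$label[i] %in% c(0, 1)) {
      stop_config("subject %s: non-binary label %s", sid, format(man$label[i]))
    }
    imgs <- list()
    for (k in VIEW_KEYS) {
      f <- file.path(base, man[[paste0("img_", k)]][i])
      if (!file.exists(f)) {
        stop_config("subject %s: image file missing: %s", sid, f)
      }
      px <- png::readPNG(f)
      if (length(dim(px)) == 3L) px <- px[, , 1]  # tolerate gray-as-RGB
      imgs[[k]] <- plaque_image(
        matrix(as.integer(round(255 * px)), nrow(px), ncol(px)),
        side = substr(k, 1, 1),
        section = if (substr(k, 2, 2) == "T") "transverse" else "longitudinal"
      )
    }
    records[[i]] <- subject_record(sid, as.integer(man$label[i]), imgs)
  }
  structure(records, class = c("plaque_cohort", "list"))
}

#' Augmentation recipe
#'
#' The default recipe is the original image plus four rescaled variants
#' (factors 0.8, 0.9, 1.1, 1.2) and a horizontal and a vertical flip: a
#' seven-fold enlargement. All four views of a subject receive the same
#' transform, and labels are preserved.
#'
#' @param scale_factors Positive rescaling factors (bilinear, output size
#'   rounded to the nearest integer).
#' @param flips Subset of `c("horizontal", "vertical")`.
#' @param include_original Keep the untransformed subject as a variant.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(scale_factors = c(0.8, 0.9, 1.1, 1.2),
                              flips = c("horizontal", "vertical"),
                              include_original = TRUE) {
  if (length(scale_factors) && any(!is.finite(scale_factors) | scale_factors <= 0)) {
    stop_config("scale_factors must all be positive")
  }
  if (length(flips)) flips <- match.arg(flips, several.ok = TRUE)
  structure(
    list(scale_factors = as.numeric(scale_factors),
         flips = as.character(flips),
         include_original = isTRUE(include_original)),
    class = "augmentation_spec"
  )
}

#' Number of variants per subject under a recipe
#' @param spec An [augmentation_spec()].
#' @return Integer multiplier (7 for the default recipe).
#' @export
augmentation_multiplier <- function(spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  length(spec$scale_factors) + length(spec$flips) +
    as.integer(spec$include_original)
}

# Bilinear rescale of one 8-bit image matrix; target dims round(f * dims).
rescale_pixels <- function(pixels, f) {
  h <- as.integer(round(f * nrow(pixels)))
  w <- as.integer(round(f * ncol(pixels)))
  out <- EBImage::resize(pixels / 255, w = h, h = w)  # EBImage dim1 = our rows
  matrix(as.integer(round(255 * pmin(pmax(out, 0), 1))), h, w)
}

flip_pixels <- function(pixels, direction) {
  if (direction == "horizontal") {
    pixels[, rev(seq_len(ncol(pixels))), drop = FALSE]
  } else {
    pixels[rev(seq_len(nrow(pixels))), , drop = FALSE]
  }
}

transform_record <- function(rec, tag, fun) {
  imgs <- lapply(rec$images, function(img) {
    plaque_image(fun(img$pixels), side = img$side, section = img$section)
  })
  subject_record(paste0(rec$subject_id, "__", tag), rec$label, imgs)
}

#' Augment a cohort with subject-consistent scales and flips
#'
#' Each subject yields one variant per recipe entry; a scaled variant scales
#' all four views by the same factor and a flipped variant flips all four the
#' same way. Variant IDs are the source ID suffixed with `__<tag>` so that
#' [base_subject_id()] recovers the source subject (used by the
#' cross-validation leakage guard). A scale that would shrink any view below
#' the minimum accepted input size is an error naming the subject.
#'
#' @param records A `plaque_cohort` or list of [subject_record()]s.
#' @param spec An [augmentation_spec()].
#' @return A `plaque_cohort` of `length(records) * augmentation_multiplier(spec)`
#'   records.
#' @export
augment_cohort <- function(records, spec = augmentation_spec()) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (!length(records)) stop_config("cannot augment an empty cohort")
  m <- osfp_min_input()
  out <- vector("list", length(records) * augmentation_multiplier(spec))
  j <- 0L
  for (rec in records) {
    if (spec$include_original) {
      j <- j + 1L
      out[[j]] <- rec
    }
    for (f in spec$scale_factors) {
      for (img in rec$images) {
        if (round(f * img$height) < m || round(f * img$width) < m) {
          stop_config(paste0("subject %s: scale %.2f would shrink a %dx%d view ",
                             "below the minimum input size %d"),
                      rec$subject_id, f, img$height, img$width, m)
        }
      }
      j <- j + 1L
      out[[j]] <- transform_record(rec, sprintf("s%g", f),
                                   function(p) rescale_pixels(p, f))
    }
    for (d in spec$flips) {
      j <- j + 1L
      out[[j]] <- transform_record(rec, substr(d, 1, 2),
                                   function(p) flip_pixels(p, d))
    }
  }
  structure(out, class = c("plaque_cohort", "list"))
}

#' Source subject of a (possibly augmented) record ID
#' @param subject_id Character vector of subject IDs.
#' @return IDs with any `__<tag>` augmentation suffix removed.
#' @export
base_subject_id <- function(subject_id) {
  sub("__.*$", "", subject_id)
}

#' Serve a cohort as single-subject batches
#'
#' Because the four views of different subjects have different pixel
#' dimensions and are deliberately never padded or resized to a common shape,
#' the network consumes exactly one subject per optimization step (batch
#' size 1). Intensities are rescaled from 8-bit to \[0, 1\] at this point.
#'
#' @param records A `plaque_cohort` or list of [subject_record()]s.
#' @param shuffle_seed Optional integer; if given, batch order is a seeded
#'   permutation (identical across runs), otherwise cohort order is kept.
#' @return A list of batches, each a list with `subject_id`, `label`, and
#'   `images`: the four numeric matrices in fixed path order LT, LL, RT, RL.
#' @export
subject_batches <- function(records, shuffle_seed = NULL) {
  idx <- seq_along(records)
  if (!is.null(shuffle_seed)) {
    idx <- with_seed(shuffle_seed, sample(idx))
  }
  lapply(idx, function(i) {
    rec <- records[[i]]
    list(subject_id = rec$subject_id,
         label = rec$label,
         images = lapply(rec$images[VIEW_KEYS],
                         function(img) img$pixels / 255))
  })
}
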