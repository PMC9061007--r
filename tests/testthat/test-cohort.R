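test_that("cohort generation is deterministic and structurally complete", {
  co <- small_cohort()
  expect_length(co, 10)
  expect_equal(n_images(co), 40)
  labs <- vapply(co, `[[`, 0L, "label")
  expect_equal(sum(labs == 1L), round(10 * 117 / 333))
  # four distinct views per subject, correct side/section metadata
  for (rec in co) {
    expect_named(rec$images, c("LT", "LL", "RT", "RL"))
    expect_equal(rec$images$RT$side, "R")
    expect_equal(rec$images$LL$section, "longitudinal")
  }
  co2 <- generate_cohort(cohort_spec(n_subjects = 10, seed = 7))
  expect_identical(co, co2)
  co3 <- generate_cohort(cohort_spec(n_subjects = 10, seed = 8))
  expect_false(identical(co, co3))
})

test_that("generated ROI geometry honours section-specific shape invariants", {
  co <- small_cohort()
  for (rec in co) {
    for (img in rec$images) {
      expect_gte(img$height, osfp_min_input())
      expect_gte(img$width, osfp_min_input())
      r <- img$width / img$height
      if (img$section == "transverse") {
        expect_gte(r, 0.75 / 1.01)
        expect_lte(r, 1.33 * 1.01)
      } else {
        expect_gte(r, 2)
      }
      expect_true(all(img$pixels >= 0L & img$pixels <= 255L))
    }
  }
})

test_that("ROI side lengths are uniform over their configured ranges", {
  spec <- cohort_spec(n_subjects = 10, seed = 1)
  draws_t <- withr::with_seed(42, replicate(1000,
    osfpnet:::draw_transverse_dims(spec$transverse_size_range)[1]))
  tab <- table(factor(draws_t, levels = 48:160))
  p_t <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p_t, 0.01)
  draws_l <- withr::with_seed(43, replicate(1000,
    osfpnet:::draw_longitudinal_dims(spec$longitudinal_height_range,
                                     spec$longitudinal_aspect_range)[1]))
  p_l <- suppressWarnings(chisq.test(table(factor(draws_l, levels = 48:96)))$p.value)
  expect_gt(p_l, 0.01)
})

test_that("effect size separates class echogenicity in the stated direction", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, seed = 31))
  labs <- vapply(co, `[[`, 0L, "label")
  means <- vapply(co, function(r) mean(vapply(r$images, function(i)
    mean(i$pixels), 0)), 0)
  # asymptomatic (0) strictly brighter than symptomatic (1)
  tt <- t.test(means[labs == 0], means[labs == 1], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_gt(mean(means[labs == 0]), mean(means[labs == 1]))
})

test_that("zero effect size yields statistically indistinguishable classes", {
  co <- generate_cohort(cohort_spec(n_subjects = 100, effect_size = 0,
                                    seed = 13))
  labs <- vapply(co, `[[`, 0L, "label")
  means <- vapply(co, function(r) mean(vapply(r$images, function(i)
    mean(i$pixels), 0)), 0)
  tt <- t.test(means[labs == 0], means[labs == 1])
  expect_gt(tt$p.value, 0.01)
})

test_that("writing and reloading a cohort round-trips exactly", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_equal(nrow(read.csv(manifest)), 10)
  expect_length(list.files(dir, pattern = "\\.png$"), 40)
  back <- load_manifest(manifest)
  expect_length(back, 10)
  expect_identical(lapply(co, unclass), lapply(back, unclass))
})

test_that("manifest loading reports broken rows by subject", {
  co <- augmentable_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  file.remove(file.path(dir, "S0002_RT.png"))
  expect_error(load_manifest(manifest), "S0002")
  manifest2 <- file.path(dir, "bad.csv")
  man <- read.csv(manifest)
  man$label[1] <- 2
  write.csv(man, manifest2, row.names = FALSE)
  expect_error(load_manifest(manifest2), "non-binary")
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_subjects = 4), ">= 5")
  expect_error(cohort_spec(transverse_size_range = c(160, 48)), "min <= max")
  expect_error(cohort_spec(transverse_size_range = c(20, 160)), "below")
  expect_error(cohort_spec(longitudinal_aspect_range = c(1.5, 5)), "min >= 2")
  expect_error(cohort_spec(symptomatic_fraction = 0), "0, 1")
  expect_error(cohort_spec(effect_size = -1), "nonnegative")
})
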