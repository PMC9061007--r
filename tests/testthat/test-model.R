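test_that("classifier input length follows 2*14k + 2*6k", {
  expect_equal(classifier_input_length(osfp_config()), 20480L)       # k = 512
  expect_equal(classifier_input_length(osfp_config_tiny()), 2560L)   # k = 64
  expect_equal(classifier_input_length(micro_config()), 4L * 40L)    # k = 4
})

test_that("per-path descriptors have the advertised 14k / 6k lengths", {
  fe <- build_backbone(backbone_config(width_scale = 0.125), seed = 1)
  k <- backbone_k(fe$cfg)
  fm_t <- extract_features(fe, random_image(64, 64, seed = 1))
  fm_l <- extract_features(fe, random_image(48, 170, seed = 2))
  expect_length(pool_features(fm_t, pooling_spec("spp")), 14 * k)
  expect_length(pool_features(fm_l, pooling_spec("msp")), 6 * k)
})

test_that("forward pass accepts arbitrary sizes and is deterministic", {
  w <- init_osfp_weights(micro_config(), seed = 3)
  imgs <- list(random_image(64, 64, 1), random_image(48, 160, 2),
               random_image(80, 80, 3), random_image(48, 200, 4))
  s1 <- osfp_scores(w, imgs)
  expect_length(s1, 2)
  expect_identical(s1, osfp_scores(w, imgs))
  expect_error(osfp_scores(w, imgs[1:3]), "4 view")
})

test_that("score shape is invariant over randomized input sizes", {
  w <- init_osfp_weights(micro_config(), seed = 5)
  set.seed(77)
  lens <- replicate(50, {
    hs <- sample(48:90, 2, replace = TRUE)
    imgs <- list(random_image(hs[1], hs[1]),
                 random_image(48, sample(96:200, 1)),
                 random_image(hs[2], hs[2]),
                 random_image(48, sample(96:200, 1)))
    length(osfp_scores(w, imgs))
  })
  expect_true(all(lens == 2))
})

test_that("dropout follows the Bernoulli retention contract", {
  y <- runif(100)
  expect_identical(apply_dropout(y, 1, "inference"), y)
  expect_equal(as.numeric(apply_dropout(y, 1, "train")), y)
  expect_equal(as.numeric(apply_dropout(y, 0, "train")), rep(0, 100))
  out <- apply_dropout(rep(1, 1e5), 0.5, "train", seed = 11)
  mask <- attr(out, "mask")
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(mean(mask) - 0.5), 3 * se)
  # inverted scaling: kept entries are 1/p
  expect_true(all(out[mask == 1] == 2))
  expect_error(apply_dropout(y, 1.2, "train"), "\\[0, 1\\]")
})

test_that("retention 1 makes training forward equal inference forward", {
  cfg <- micro_config(dropout_drop = 0)
  w <- init_osfp_weights(cfg, seed = 2)
  imgs <- list(random_image(48, 48, 1), random_image(48, 100, 2),
               random_image(48, 48, 3), random_image(48, 100, 4))
  tr <- osfpnet:::osfp_forward(w, imgs, mode = "train")
  expect_equal(tr$logits, osfpnet:::osfp_forward(w, imgs, mode = "inference"))
})

test_that("tied backbones give identical transverse-path descriptors", {
  cfg <- micro_config(tie_fe_weights = TRUE)
  w <- init_osfp_weights(cfg, seed = 4)
  expect_length(w$fes, 1)
  img <- random_image(60, 60, seed = 9)
  d1 <- pool_features(extract_features(osfpnet:::path_fe(w, 1), img),
                      cfg$pooling_transverse)
  d3 <- pool_features(extract_features(osfpnet:::path_fe(w, 3), img),
                      cfg$pooling_transverse)
  expect_identical(d1, d3)
})

test_that("checkpoints round-trip weights and path order", {
  w <- init_osfp_weights(micro_config(), seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(w, path)
  w2 <- load_checkpoint(path)
  expect_identical(w, w2)
  imgs <- list(random_image(48, 48, 1), random_image(48, 100, 2),
               random_image(48, 48, 3), random_image(48, 100, 4))
  expect_identical(osfp_scores(w, imgs), osfp_scores(w2, imgs))
})

test_that("model configuration is validated", {
  expect_error(osfp_config(pooling_transverse = pooling_spec("msp"),
                           pooling_longitudinal = pooling_spec("msp")),
               "SPP")
  expect_error(osfp_config(dropout_drop = 1.5), "\\[0, 1\\]")
})
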