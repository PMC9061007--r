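test_that("the default pyramid has 14 bins and the default strips have 6", {
  expect_equal(pooling_units(pooling_spec("spp")), 14L)
  expect_equal(pooling_units(pooling_spec("msp")), 6L)
})

test_that("adaptive bin edges follow the floor-start/ceil-end convention", {
  expect_equal(adaptive_bin_edges(4, 2),
               cbind(start = c(0, 2), end = c(2, 4)))
  expect_equal(adaptive_bin_edges(5, 3),
               cbind(start = c(0, 1, 3), end = c(2, 4, 5)))
  expect_equal(adaptive_bin_edges(3, 3),
               cbind(start = c(0, 1, 2), end = c(1, 2, 3)))
  expect_error(adaptive_bin_edges(2, 3), "extent >= n_bins")
  # bins always cover the full extent
  for (extent in 3:9) {
    for (n in 1:extent) {
      e <- adaptive_bin_edges(extent, n)
      covered <- sort(unique(unlist(Map(function(s, t) s:(t - 1),
                                        e[, "start"], e[, "end"]))))
      expect_equal(covered, 0:(extent - 1))
    }
  }
})

test_that("descriptor length is k * units regardless of map size", {
  set.seed(4)
  for (spec in list(pooling_spec("spp"), pooling_spec("msp"))) {
    for (i in 1:8) {
      h <- sample(3:20, 1); w <- sample(3:40, 1); k <- sample(1:6, 1)
      fmap <- array(rnorm(h * w * k), c(h, w, k))
      expect_length(pool_features(fmap, spec), k * pooling_units(spec))
    }
  }
  # the full-width configuration: 512-channel maps of different sizes
  for (d in list(c(3, 3), c(9, 30))) {
    fmap <- array(rnorm(d[1] * d[2] * 512), c(d, 512))
    expect_length(pool_features(fmap, pooling_spec("spp")), 7168)
    expect_length(pool_features(fmap, pooling_spec("msp")), 3072)
  }
})

test_that("pooling a channel-constant map returns that constant in every unit", {
  k <- 3
  const <- c(1.5, -2, 0.25)
  fmap <- array(rep(const, each = 20), c(4, 5, k))
  for (spec in list(pooling_spec("spp"), pooling_spec("msp"),
                    pooling_spec("spp", operator = "average"),
                    pooling_spec("msp", operator = "max"))) {
    v <- pool_features(fmap, spec)
    # layout: levels in order; channels contiguous within a level
    off <- 0
    for (lev in spec$levels) {
      nb <- lev[1] * lev[2]
      lv <- v[(off + 1):(off + k * nb)]
      expect_equal(lv, rep(const, each = nb))
      off <- off + k * nb
    }
  }
})

test_that("max pooling is monotone under elementwise increase", {
  set.seed(8)
  fmap <- array(rnorm(5 * 7 * 2), c(5, 7, 2))
  bigger <- fmap + abs(array(rnorm(5 * 7 * 2), c(5, 7, 2)))
  for (spec in list(pooling_spec("spp"), pooling_spec("msp", operator = "max"))) {
    expect_true(all(pool_features(bigger, spec) >=
                      pool_features(fmap, spec)))
  }
})

test_that("pooling agrees with brute-force bin enumeration on small maps", {
  set.seed(21)
  for (i in 1:20) {
    h <- sample(3:8, 1); w <- sample(3:8, 1); k <- sample(1:3, 1)
    fmap <- array(rnorm(h * w * k), c(h, w, k))
    for (spec in list(pooling_spec("spp"), pooling_spec("msp"),
                      pooling_spec("spp", operator = "average"),
                      pooling_spec("msp", operator = "max"))) {
      expect_equal(pool_features(fmap, spec),
                   brute_force_pool(fmap, spec$levels, spec$operator))
    }
  }
})

test_that("maps smaller than the finest grid are rejected", {
  fmap <- array(rnorm(2 * 5 * 1), c(2, 5, 1))
  expect_error(pool_features(fmap, pooling_spec("spp")), "finest")
  expect_error(pool_features(array(0, c(2, 1, 1)), pooling_spec("msp")),
               "finest")
})

test_that("pooling specs are validated", {
  expect_error(pooling_spec("spp", levels = list(c(2, 3))), "square")
  expect_error(pooling_spec("msp", levels = list(c(2, 2))), "strips")
  expect_error(pooling_spec("spp", levels = list(c(0, 0))), "positive")
})
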