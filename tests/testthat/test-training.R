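test_that("learning rate follows the staircase decay", {
  ctrl <- train_control()
  expect_equal(lr_at_epoch(ctrl, 0), 0.001)
  expect_equal(lr_at_epoch(ctrl, 5), 0.001)
  expect_equal(lr_at_epoch(ctrl, 6), 0.0001)
  expect_equal(lr_at_epoch(ctrl, 29), 1e-7)
  # closed form over the whole run
  for (e in 0:29) {
    expect_equal(lr_at_epoch(ctrl, e), 0.001 / 10^(e %/% 6))
  }
  expect_error(lr_at_epoch(ctrl, 30), "\\[0, 30\\)")
  expect_error(lr_at_epoch(ctrl, -1), "\\[0, 30\\)")
})

test_that("batch sizes above one are rejected", {
  expect_error(train_control(batch_size = 2), "heterogeneous")
})

test_that("333 subjects split into five folds of 65-70 summing to 333", {
  ids <- sprintf("P%03d", 1:333)
  fa <- make_folds(ids, seed = 4)
  expect_s3_class(fa, "fold_assignment")
  expect_length(fa$sizes, 5)
  expect_true(all(fa$sizes >= 65 & fa$sizes <= 70))
  expect_equal(sum(fa$sizes), 333)
  expect_setequal(names(fa$fold_of), ids)
  # every subject in exactly one fold, counts match the drawn sizes
  expect_equal(as.integer(table(factor(fa$fold_of, levels = 1:5))), fa$sizes)
  # held-out arithmetic: training set is the complement
  expect_equal(333 - fa$sizes[fa$sizes == 66][1], 267)
  expect_identical(fa, make_folds(ids, seed = 4))
  expect_false(identical(fa$fold_of, make_folds(ids, seed = 5)$fold_of))
})

test_that("five subjects fall back to singleton folds", {
  fa <- make_folds(letters[1:5], seed = 1)
  expect_equal(sort(fa$sizes), rep(1L, 5))
})

test_that("infeasible size bands warn and split near-equally", {
  expect_warning(fa <- make_folds(sprintf("x%02d", 1:7), seed = 1),
                 "near-equal")
  expect_equal(sum(fa$sizes), 7)
  expect_lte(max(fa$sizes) - min(fa$sizes), 1)
})

test_that("training and validation subjects must be disjoint", {
  co <- small_cohort()
  expect_error(osfp_net(co[1:6], model = micro_config(),
                        control = train_control(epochs = 0),
                        validation = co[5:8]),
               "protocol")
  # augmented variants of a validation subject are caught too
  co60 <- augmentable_cohort()
  aug <- augment_cohort(co60[1:3])
  expect_error(osfp_net(aug, model = micro_config(),
                        control = train_control(epochs = 0),
                        validation = co60[3:4]),
               "protocol")
})

test_that("zero epochs leave the initialized weights untouched", {
  co <- small_cohort()
  fit <- osfp_net(co, model = micro_config(),
                  control = train_control(epochs = 0, seed = 21),
                  standardize_init = FALSE)
  expect_identical(fit$weights, init_osfp_weights(micro_config(), seed = 21))
  expect_equal(nrow(fit$history), 0)
  # with data-dependent init, refitting reproduces the same starting point
  fit2 <- osfp_net(co, model = micro_config(),
                   control = train_control(epochs = 0, seed = 21))
  fit3 <- osfp_net(co, model = micro_config(),
                   control = train_control(epochs = 0, seed = 21))
  expect_identical(fit2$weights, fit3$weights)
})

test_that("one training epoch runs, logs, and is reproducible", {
  co <- small_cohort()
  ctrl <- train_control(epochs = 1, seed = 31)
  fit1 <- osfp_net(co, model = micro_config(), control = ctrl)
  fit2 <- osfp_net(co, model = micro_config(), control = ctrl)
  expect_equal(nrow(fit1$history), 1)
  expect_true(is.finite(fit1$history$loss))
  expect_identical(fit1$weights, fit2$weights)
  pred <- predict(fit1, co[1:3], type = "prob")
  expect_length(pred, 3)
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("cross-validation partitions subjects and never leaks", {
  co <- small_cohort()
  cv <- osfp_cv(co, model = micro_config(),
                control = train_control(epochs = 0, seed = 1),
                k = 5, fold_seed = 2)
  preds <- cv$predictions
  # every subject appears in exactly one test fold
  expect_setequal(preds$subject_id, vapply(co, `[[`, "", "subject_id"))
  expect_equal(nrow(preds), 10)
  expect_equal(anyDuplicated(preds$subject_id), 0)
  # K5 protocol: each round tests ~20% of subjects
  expect_equal(as.integer(table(preds$fold)), cv$folds$sizes)
  expect_equal(nrow(cv$metrics), 5)
  # averaging identical per-fold values is the identity
  expect_equal(unname(cv$mean_metrics["accuracy"]),
               mean(cv$metrics$accuracy, na.rm = TRUE))
  # augmented input is refused
  expect_error(osfp_cv(augment_cohort(augmentable_cohort()),
                       model = micro_config(),
                       control = train_control(epochs = 0)),
               "unaugmented")
})
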