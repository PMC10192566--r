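# Training-protocol unit tests use very short schedules: they check the
# protocol (folds, partition, determinism, leakage), not the learning.

fast_cfg <- function(...) compact_train_config(epochs = 2L, ...)

test_that("training configuration is validated by field name", {
  expect_error(train_config(lambda_adv = -1), "TrainConfig.lambda_adv")
  expect_error(train_config(epochs = 0), "TrainConfig.epochs")
  expect_error(train_config(validation_fraction = 1),
               "TrainConfig.validation_fraction")
  expect_error(train_config(lr = 0), "TrainConfig.lr")
  expect_error(train_config(disc_steps = 0), "TrainConfig.disc_steps")
})

test_that("leave-one-episode-out produces one fold per episode with a perfect test partition", {
  ds <- quick_dataset(seg_s = 15, n_episodes = 4, seed = 3)
  run <- loocv(ds, fast_cfg(seed = 2), compact_branch_config(),
               keep_fits = FALSE)
  expect_length(run$reports, 4)
  expect_equal(vapply(run$reports, `[[`, integer(1), "held_out_episode"),
               0:3)
  tested <- sort(unlist(lapply(run$predictions, `[[`, "index")))
  expect_equal(tested, seq_along(ds$y))       # every segment in exactly one fold
  for (p in run$predictions) {
    expect_true(all(ds$d[p$index] == p$episode))
  }
})

test_that("patients with fewer than three episodes are refused", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  ds2 <- ds
  keep <- ds2$d < 2
  ds2$eeg <- ds2$eeg[keep, , , drop = FALSE]
  ds2$scal <- ds2$scal[keep, , , drop = FALSE]
  ds2$ecg <- ds2$ecg[keep, , drop = FALSE]
  ds2$y <- ds2$y[keep]; ds2$d <- ds2$d[keep]
  expect_error(loocv(ds2, fast_cfg(), compact_branch_config()),
               "at least three episodes")
})

test_that("a training fold containing only one class is refused", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  ds1 <- ds
  ds1$y[ds1$d != 2] <- 0L                     # degenerate training labels
  expect_error(train_fold(ds1, 2L, fast_cfg(), compact_branch_config()),
               "degenerate labels")
})

test_that("training is deterministic under a fixed seed", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  f1 <- train_fold(ds, 0L, fast_cfg(seed = 77), compact_branch_config())
  f2 <- train_fold(ds, 0L, fast_cfg(seed = 77), compact_branch_config())
  expect_identical(seizefuse:::net_get_params(f1$branch_eeg$extractor),
                   seizefuse:::net_get_params(f2$branch_eeg$extractor))
  expect_identical(f1$weights, f2$weights)
  p1 <- predict(f1, ds, which(ds$d == 0L))
  p2 <- predict(f2, ds, which(ds$d == 0L))
  expect_identical(p1$prob, p2$prob)
})

test_that("no statistic of the held-out episode influences training", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  poisoned <- ds
  sent <- ds$d == 2L
  poisoned$eeg[sent, , ] <- 1e6               # sentinel values
  poisoned$scal[sent, , ] <- -1e6
  poisoned$ecg[sent, ] <- 1e6
  f1 <- train_fold(ds, 2L, fast_cfg(seed = 5), compact_branch_config())
  f2 <- train_fold(poisoned, 2L, fast_cfg(seed = 5), compact_branch_config())
  expect_identical(seizefuse:::net_get_params(f1$branch_eeg$extractor),
                   seizefuse:::net_get_params(f2$branch_eeg$extractor))
  expect_identical(seizefuse:::net_get_params(f1$branch_ecg$head),
                   seizefuse:::net_get_params(f2$branch_ecg$head))
  expect_identical(f1$weights, f2$weights)
})

test_that("an extreme adversarial weight still yields finite metrics", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  fit <- train_fold(ds, 2L, fast_cfg(lambda_adv = 10, seed = 8),
                    compact_branch_config())
  pr <- predict(fit, ds, which(ds$d == 2L))
  expect_true(all(is.finite(pr$prob)))
  expect_true(all(is.finite(as.matrix(fit$history[, c("L_c", "L_d_eeg", "L_d_ecg")]))))
})

test_that("ablation fusion modes train end to end", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  for (mode in c("data", "feature")) {
    fit <- train_fold(ds, 2L, fast_cfg(fusion = mode, seed = 4),
                      compact_branch_config())
    pr <- predict(fit, ds, which(ds$d == 2L))
    expect_equal(dim(pr$prob), c(sum(ds$d == 2L), 2))
    expect_equal(rowSums(pr$prob), rep(1, sum(ds$d == 2L)), tolerance = 1e-9)
  }
})

test_that("fixed- and learned-weight modes are honoured", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  ff <- train_fold(ds, 2L, fast_cfg(weights = "fixed", seed = 4),
                   compact_branch_config())
  expect_equal(ff$weights$W1, 0.5)
  fl <- train_fold(ds, 2L, fast_cfg(weights = "learned", seed = 4),
                   compact_branch_config())
  expect_equal(fl$weights$W1 + fl$weights$W2, 1, tolerance = 1e-9)
})

test_that("the training history logs the quantities the protocol derives", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  fit <- train_fold(ds, 1L, fast_cfg(seed = 6), compact_branch_config())
  h <- fit$history
  expect_equal(nrow(h), 2)
  expect_true(all(c("L_c", "L_d_eeg", "L_d_ecg", "err1", "err2",
                    "W1", "W2", "val_err") %in% names(h)))
  # fold weights equal the dynamic-weight formula on the best epoch errors
  best <- h[fit$best_epoch, ]
  w <- dynamic_weights(best$err1, best$err2)
  expect_equal(fit$weights$W1, w$W1, tolerance = 1e-12)
  # discriminator classes are the training episodes only
  expect_equal(fit$train_episodes, c(0L, 2L))
})

test_that("center loss can be enabled and alters training", {
  ds <- quick_dataset(seg_s = 15, seed = 3)
  f0 <- train_fold(ds, 2L, fast_cfg(seed = 9), compact_branch_config())
  f1 <- train_fold(ds, 2L,
                   fast_cfg(seed = 9,
                            center_loss = list(enabled = TRUE, weight = 0.05,
                                               lr = 0.05)),
                   compact_branch_config())
  expect_false(identical(
    seizefuse:::net_get_params(f0$branch_eeg$extractor),
    seizefuse:::net_get_params(f1$branch_eeg$extractor)))
  expect_true(all(is.finite(f1$centers[[1]])))
})
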