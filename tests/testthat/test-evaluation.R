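test_that("confusion counts match hand tallies", {
  cc <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))

  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  p <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  cc <- confusion_counts(y, p)
  expect_equal(cc$TP, 3); expect_equal(cc$FN, 2)
  expect_equal(cc$TN, 4); expect_equal(cc$FP, 1)

  expect_error(confusion_counts(integer(0), integer(0)), "empty")
  expect_error(confusion_counts(c(1, 0), c(1)), "mismatch")
  expect_error(confusion_counts(c(2, 0), c(1, 0)), "0 or 1")
})

test_that("metrics follow both specificity conventions", {
  cc <- confusion_counts(c(rep(1, 5), rep(0, 5)),
                         c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1))
  m <- classification_metrics(cc)
  expect_equal(m$acc, 0.7)
  expect_equal(m$sn, 0.6)
  expect_equal(m$sp, 0.8)                    # TN / (TN + FP)
  m2 <- classification_metrics(cc, sp_definition = "as-printed")
  expect_equal(m2$sp, 4 / 7)                 # TN / (TP + TN)

  perfect <- confusion_counts(c(1, 0), c(1, 0))
  mp <- classification_metrics(perfect)
  expect_equal(unlist(mp), c(acc = 1, sn = 1, sp = 1))
  # the as-printed denominator mixes TP into specificity, so even a perfect
  # prediction scores TN / (TP + TN) = 0.5 here — the formula's own value
  expect_equal(classification_metrics(perfect, "as-printed")$sp, 0.5)

  # zero denominators flag the metric as undefined, never 0
  allneg <- confusion_counts(c(0, 0), c(0, 0))
  expect_true(is.na(classification_metrics(allneg)$sn))
  allpos <- confusion_counts(c(1, 1), c(1, 1))
  expect_true(is.na(classification_metrics(allpos)$sp))
})

test_that("metrics agree with an independent reference on random tables", {
  skip_if_not_installed("caret")
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    p <- ifelse(runif(n) < 0.3, 1 - y, y)    # noisy predictions
    if (length(unique(y)) < 2) next
    cc <- confusion_counts(y, p)
    m <- classification_metrics(cc)
    ref <- caret::confusionMatrix(factor(p, levels = c(0, 1)),
                                  factor(y, levels = c(0, 1)),
                                  positive = "1")
    expect_equal(m$acc, unname(ref$overall["Accuracy"]), tolerance = 1e-12)
    expect_equal(m$sn, unname(ref$byClass["Sensitivity"]), tolerance = 1e-12)
    expect_equal(m$sp, unname(ref$byClass["Specificity"]), tolerance = 1e-12)
  }
})

test_that("false alarm rate counts alarms per interictal window", {
  expect_equal(false_alarm_rate(c(rep(0, 98), 1, 1))$far, 0.02)
  expect_equal(false_alarm_rate(rep(0, 50))$far, 0)
  out <- false_alarm_rate(integer(0))
  expect_true(is.na(out$far))
  expect_equal(out$n_wo, 0)
})

test_that("FAR equals 1 - specificity on the same predictions", {
  set.seed(11)
  y <- rbinom(200, 1, 0.5)
  p <- ifelse(runif(200) < 0.2, 1 - y, y)
  r <- fold_report(y, p)
  expect_equal(r$far, 1 - r$sp, tolerance = 1e-12)
})

test_that("aggregation reports mean, sd and pooled metrics", {
  r1 <- fold_report(c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0),
                    c(1, 1, 0, 0, 1, 1, 0, 0, 0, 0), held_out_episode = 0)
  r2 <- fold_report(c(1, 0), c(1, 0), held_out_episode = 1)
  expect_equal(r1$acc, 0.9)
  ag <- aggregate_folds(list(r1, r2))
  expect_equal(ag$mean$acc, 0.95)
  expect_equal(ag$sd$acc, stats::sd(c(0.9, 1)), tolerance = 1e-12)
  expect_equal(ag$sd$acc, 0.0707, tolerance = 1e-3)
  expect_equal(ag$pooled$acc, 11 / 12)
  # single fold -> sd 0
  expect_equal(aggregate_folds(list(r1))$sd$acc, 0)
  expect_error(aggregate_folds(list()), "no fold")
})
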