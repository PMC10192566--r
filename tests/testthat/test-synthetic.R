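test_that("identical specs give byte-identical recordings", {
  spec <- synthetic_spec(seg_seconds_per_state = 10, seed = 7)
  a <- generate_patient(spec)
  b <- generate_patient(spec)
  expect_identical(a, b)
})

test_that("episode substreams are stable when episodes are added", {
  s3 <- synthetic_spec(n_episodes = 3, seg_seconds_per_state = 10, seed = 11)
  s4 <- synthetic_spec(n_episodes = 4, seg_seconds_per_state = 10, seed = 11)
  r3 <- generate_patient(s3)
  r4 <- generate_patient(s4)
  # the last episode differs by design (its class association flips), but
  # earlier episodes must be untouched by extending the patient
  for (k in 1:2) expect_identical(r3[[k]]$eeg, r4[[k]]$eeg)
})

test_that("recordings have the documented structure", {
  spec <- synthetic_spec(n_episodes = 3, seg_seconds_per_state = 10, seed = 2)
  recs <- generate_patient(spec)
  expect_length(recs, 3)
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    expect_s3_class(r, "sz_recording")
    expect_equal(r$episode_id, k - 1L)
    ns <- 10 * spec$fs
    expect_equal(dim(r$eeg), c(spec$n_eeg_channels, 2 * ns))
    expect_length(r$ecg, 2 * ns)
    expect_equal(r$state_intervals$state, c("interictal", "preictal"))
    expect_equal(r$state_intervals$start, c(0L, ns))
    expect_equal(r$state_intervals$end, c(ns, 2L * ns))
  }
})

test_that("invalid spec fields are rejected by name", {
  expect_error(synthetic_spec(fs = -1), "fs")
  expect_error(synthetic_spec(eeg_effect = -0.5), "eeg_effect")
  expect_error(synthetic_spec(n_episodes = 0), "n_episodes")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})

test_that("EEG class separability is monotone in eeg_effect (bandpower AUC)", {
  aucs <- vapply(c(0, 0.4, 0.8, 1.6), function(eff) {
    recs <- generate_patient(synthetic_spec(
      n_episodes = 3, seg_seconds_per_state = 30, episode_shift = 0,
      eeg_effect = eff, ecg_effect = 0, seed = 21))
    score <- c(); y <- c()
    for (r in recs) {
      seg <- segment_windows(r)
      score <- c(score, vapply(seq_along(seg$y), function(i) {
        band_power(seg$eeg[i, , ], r$fs, 3.5, 6.5)
      }, numeric(1)))
      y <- c(y, seg$y)
    }
    rank_auc(score, y)
  }, numeric(1))
  # windows of the same noise stream are autocorrelated, so the effective
  # sample size is below the window count; allow generous MC tolerance
  expect_lt(abs(aucs[1] - 0.5), 0.12)        # null effect is at chance
  expect_true(all(diff(aucs) > -0.03))       # non-decreasing within MC noise
  expect_gt(aucs[4], 0.95)
})

test_that("episode shift is detectable from interictal segments only", {
  skip_if_not_installed("nnet")
  probe <- function(shift) {
    recs <- generate_patient(synthetic_spec(
      n_episodes = 3, seg_seconds_per_state = 30, episode_shift = shift,
      eeg_effect = 0.8, ecg_effect = 0, seed = 33))
    feats <- list(); d <- c()
    for (r in recs) {
      seg <- segment_windows(r)
      keep <- seg$y == 0L
      f <- t(vapply(which(keep), function(i) {
        c(band_power(seg$eeg[i, , ], r$fs, 7, 13),
          band_power(seg$eeg[i, , ], r$fs, 14, 18))
      }, numeric(2)))
      feats[[length(feats) + 1L]] <- f
      d <- c(d, seg$d[keep])
    }
    X <- data.frame(do.call(rbind, feats)); dd <- factor(d)
    set.seed(1)
    half <- sample(nrow(X), nrow(X) %/% 2)
    m <- nnet::multinom(dd[half] ~ ., data = X[half, , drop = FALSE],
                        trace = FALSE)
    mean(predict(m, newdata = X[-half, , drop = FALSE]) == dd[-half])
  }
  expect_gt(probe(1), 1 / 3 + 0.15)          # shifted episodes: above chance
  expect_lt(probe(0), 1 / 3 + 0.12)          # no shift: near chance
})

test_that("preictal ECG beats arrive faster in proportion to ecg_effect", {
  count_beats <- function(x, fs) {
    th <- 0.5 * max(x)
    up <- which(x[-1] > th & x[-length(x)] <= th)
    length(up)
  }
  recs <- generate_patient(synthetic_spec(
    n_episodes = 3, seg_seconds_per_state = 60, episode_shift = 0,
    eeg_effect = 0, ecg_effect = 2, noise_sd = 0.2, seed = 5))
  r <- recs[[1]]
  ns <- 60 * r$fs
  n_inter <- count_beats(r$ecg[1:ns], r$fs)
  n_pre <- count_beats(r$ecg[(ns + 1):(2 * ns)], r$fs)
  # RR shortens by factor 1 - 0.2*2 = 0.6 -> ~1/0.6 more beats
  expect_gt(n_pre / n_inter, 1.3)
})
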