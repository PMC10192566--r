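test_that("DC is removed by the 0.1 Hz high-pass", {
  # the 0.1 Hz corner has a settling time of tens of seconds, so use a
  # long record and judge the steady-state middle third
  x <- rep(5, 90 * 512)
  y <- filter_signal(x, fs = 512)
  mid <- y[(30 * 512):(60 * 512)]
  expect_lt(mean(mid^2), 1e-4 * mean(x^2))
})

test_that("the notch attenuates 50 Hz by at least 20 dB", {
  t <- seq(0, 4, by = 1 / 512)[-1]
  x <- sin(2 * pi * 50 * t)
  y <- filter_signal(x, fs = 512)
  mid <- 513:(3 * 512)
  att <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_lt(20 * log10(att), -20)
})

test_that("a 10 Hz passband tone is preserved within 5%", {
  t <- seq(0, 4, by = 1 / 512)[-1]
  x <- sin(2 * pi * 10 * t)
  y <- filter_signal(x, fs = 512)
  mid <- 513:(3 * 512)
  ratio <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("filter_signal rejects sampling rates below twice the low-pass", {
  expect_error(filter_signal(rnorm(100), fs = 128, high = 70), "fs")
})

test_that("min-max normalization follows the stated convention", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  set.seed(1)
  x <- rnorm(100)
  y <- minmax_normalize(x)
  expect_equal(range(y), c(0, 1))
  expect_equal(order(x), order(y))            # order preserved
  expect_warning(z <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
})

test_that("segmentation produces the exact window counts", {
  fs <- 512
  n <- 300 * fs
  rec <- recording(matrix(rnorm(n), 1, n), rnorm(n), fs,
                   state_intervals = data.frame(start = 0L, end = n,
                                                state = "preictal"))
  seg <- segment_windows(rec, window_s = 1, overlap = 0)
  expect_equal(dim(seg$eeg), c(300, 1, 512))
  expect_true(all(seg$y == 1L))

  # 10.5 s interval -> 10 windows, remainder dropped
  fs <- 64; n2 <- round(10.5 * fs)
  rec2 <- recording(matrix(rnorm(n2), 1, n2), rnorm(n2), fs,
                    state_intervals = data.frame(start = 0L, end = n2,
                                                 state = "interictal"))
  expect_equal(dim(segment_windows(rec2)$eeg)[1], 10)

  # 3 s interval, 1 s windows, 50% overlap -> 5 windows
  n3 <- 3 * fs
  rec3 <- recording(matrix(rnorm(n3), 1, n3), rnorm(n3), fs,
                    state_intervals = data.frame(start = 0L, end = n3,
                                                 state = "interictal"))
  expect_equal(dim(segment_windows(rec3, overlap = 0.5)$eeg)[1], 5)

  # total count = sum over intervals of floor(interval/window)
  n4 <- 20 * fs
  iv <- data.frame(start = c(0L, 10L * fs), end = c(round(7.5 * fs), 20L * fs),
                   state = c("interictal", "preictal"))
  rec4 <- recording(matrix(rnorm(n4), 1, n4), rnorm(n4), fs,
                    state_intervals = iv)
  expect_equal(dim(segment_windows(rec4)$eeg)[1], 7 + 10)

  # window longer than every interval -> empty with warning
  n5 <- fs %/% 2
  rec5 <- recording(matrix(rnorm(n5), 1, n5), rnorm(n5), fs,
                    state_intervals = data.frame(start = 0L, end = n5,
                                                 state = "interictal"))
  expect_warning(out <- segment_windows(rec5), "no segments")
  expect_equal(dim(out$eeg)[1], 0)
})

mexh_ref <- function(t) (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)

# Direct Riemann-sum evaluation of the wavelet integral in sample units.
cwt_oracle <- function(x, scales) {
  n <- length(x)
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    for (b in seq_len(n)) {
      out[si, b] <- sum(x * mexh_ref((seq_len(n) - b) / a)) / sqrt(a)
    }
  }
  out
}

test_that("the scalogram matches direct integration of the wavelet transform", {
  set.seed(42)
  scales <- c(1, 2, 5, 13, 32)
  for (k in 1:5) {
    x <- rnorm(512)
    got <- cwt_scalogram(x, scales = scales)
    want <- cwt_oracle(x, scales)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("the scalogram is linear and vanishes on zero input", {
  expect_equal(cwt_scalogram(numeric(64)), matrix(0, 32, 64))
  set.seed(3)
  x <- rnorm(64)
  expect_equal(cwt_scalogram(3.5 * x), 3.5 * cwt_scalogram(x))
  # impulse at the centre reproduces the scaled wavelet
  d <- numeric(65); d[33] <- 1
  got <- cwt_scalogram(d, scales = 4)
  want <- mexh_ref((33 - seq_len(65)) / 4) / 2
  expect_equal(as.numeric(got), want, tolerance = 1e-3)
})

test_that("the preprocessing pipeline produces consistent dataset shapes", {
  ds <- quick_dataset(seg_s = 20)
  n <- length(ds$y)
  expect_equal(n, 3 * 2 * 20)                 # 3 episodes x 40 windows
  expect_equal(dim(ds$eeg), c(n, 8, 64))
  expect_equal(dim(ds$scal), c(n, 32, 16))    # 64 samples pooled by 4
  expect_true(all(ds$eeg >= 0 & ds$eeg <= 1))
  expect_setequal(unique(ds$d), 0:2)
  expect_equal(sum(ds$y == 1), n / 2)
  expect_equal(ds$manifest$normalization,
               "per channel per recording, after filtering")
})
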