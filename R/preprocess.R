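#' Zero-phase band-pass plus notch filtering
#'
#' Band-pass realized as an order-4 Butterworth high-pass at `low` cascaded
#' with an order-4 low-pass at `high` (numerically robust for very low
#' high-pass corners), followed by an order-2 Butterworth band-stop between
#' `notch[1]` and `notch[2]` for mains interference. Every stage is applied
#' forward-backward ([signal::filtfilt]) so the net filter is zero-phase and
#' preserves the timing of labels relative to the signal.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz; must exceed `2 * high`.
#' @param low high-pass corner, Hz (default 0.1).
#' @param high low-pass corner, Hz (default 70).
#' @param notch length-2 band-stop edges in Hz (default `c(48, 52)`), or
#'   `NULL` to skip the notch.
#' @return Filtered vector, same length as `x`.
#' @export
filter_signal <- function(x, fs, low = 0.1, high = 70, notch = c(48, 52)) {
  if (fs <= 2 * high) {
    stop(sprintf("filter_signal: fs = %g Hz too low for a %g Hz low-pass (need fs > %g)",
                 fs, high, 2 * high))
  }
  ny <- fs / 2
  hp <- signal::butter(4, low / ny, type = "high")
  lp <- signal::butter(4, high / ny, type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  if (!is.null(notch)) {
    if (notch[2] >= ny) {
      stop("filter_signal: notch band reaches the Nyquist frequency")
    }
    bs <- signal::butter(2, notch / ny, type = "stop")
    y <- signal::filtfilt(bs, y)
  }
  y
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)` elementwise. A constant input has no range; by
#' convention it maps to all zeros with a warning.
#'
#' @param x numeric vector, matrix or array.
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  rng <- range(x, finite = TRUE)
  if (rng[2] - rng[1] <= 0) {
    warning("minmax_normalize: constant input, returning zeros")
    return(x * 0)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Tile state intervals with fixed-length windows
#'
#' Each populated state interval of the recording is cut into windows of
#' `round(fs * window_s)` samples with hop `round(window_samples * (1 -
#' overlap))`; a trailing partial window is dropped. Every window carries the
#' interval's class label (interictal = 0, preictal = 1) and the recording's
#' episode label.
#'
#' @param rec an `sz_recording` with `state_intervals` populated.
#' @param window_s window length, seconds (default 1).
#' @param overlap fractional overlap in `[0, 1)` (default 0).
#' @return List with `eeg` (array n x channels x window), `ecg` (matrix
#'   n x window), `y` (0/1 integer), `d` (episode label); zero windows give
#'   an empty result with a warning.
#' @export
segment_windows <- function(rec, window_s = 1, overlap = 0) {
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  iv <- rec$state_intervals
  if (!nrow(iv)) stop("segment_windows: state_intervals not populated")
  wlen <- round(rec$fs * window_s)
  hop <- max(1L, round(wlen * (1 - overlap)))
  starts <- integer(0); ys <- integer(0)
  for (i in seq_len(nrow(iv))) {
    s0 <- iv$start[i]
    last <- iv$end[i] - wlen
    if (last < s0) next
    st <- seq(s0, last, by = hop)
    starts <- c(starts, st)
    ys <- c(ys, rep(if (iv$state[i] == "preictal") 1L else 0L, length(st)))
  }
  n <- length(starts)
  if (n == 0L) {
    warning("segment_windows: window longer than every interval; no segments")
    return(list(eeg = array(0, c(0L, nrow(rec$eeg), wlen)),
                ecg = matrix(0, 0L, wlen), y = integer(0), d = integer(0)))
  }
  C <- nrow(rec$eeg)
  eeg <- array(0, c(n, C, wlen))
  ecg <- matrix(0, n, wlen)
  for (i in seq_len(n)) {
    sel <- (starts[i] + 1L):(starts[i] + wlen)
    eeg[i, , ] <- rec$eeg[, sel]
    ecg[i, ] <- rec$ecg[sel]
  }
  list(eeg = eeg, ecg = ecg, y = ys, d = rep(rec$episode_id, n))
}

# Mexican-hat (Ricker) mother wavelet.
mexh <- function(t) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)
}

#' Continuous-wavelet scalogram of a 1-second ECG window
#'
#' Computes `W(a, b) = a^{-1/2} * sum_t f(t) psi((t - b) / a)` over integer
#' scales `a` and every translation `b` inside the window, with the
#' Mexican-hat mother wavelet and time measured in samples. The signal is
#' treated as zero outside the window, and signed coefficients are kept (no
#' modulus).
#'
#' @param x numeric window.
#' @param scales integer scales (default `1:32`).
#' @param wavelet mother wavelet; only `"mexh"` is implemented.
#' @return Matrix `length(scales)` x `length(x)`, row `s` the coefficients
#'   at scale `scales[s]`.
#' @export
cwt_scalogram <- function(x, scales = 1:32, wavelet = "mexh") {
  wavelet <- match.arg(wavelet, "mexh")
  n <- length(x)
  if (n == 0L) stop("cwt_scalogram: empty window")
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    K <- ceiling(5 * a)                      # mexh support: |t| <= 5 sd
    k <- mexh((-K:K) / a) / sqrt(a)
    xp <- c(numeric(K), x, numeric(K))
    # W(a, b) = sum_tau x[b + tau] * psi(tau / a) / sqrt(a)  (psi is even)
    out[si, ] <- vapply(seq_len(n),
                        function(b) sum(xp[b:(b + 2L * K)] * k),
                        numeric(1))
  }
  out
}

# Average-pool the time axis of a scalogram by an integer factor.
#' @keywords internal
pool_scalogram_time <- function(S, factor = 4L) {
  if (factor <= 1L) return(S)
  n <- ncol(S) %/% factor
  out <- matrix(0, nrow(S), n)
  for (j in seq_len(n)) {
    out[, j] <- rowMeans(S[, ((j - 1L) * factor + 1L):(j * factor), drop = FALSE])
  }
  out
}

#' Preprocess a patient's recordings into a model-ready dataset
#'
#' Fixed pipeline per recording: filter every channel (EEG and ECG) with
#' [filter_signal()], min-max normalize per channel within the recording
#' (episode scope, so no statistic of a held-out episode can reach a
#' training fold), tile the state intervals into windows, and turn each ECG
#' window into a Mexican-hat scalogram whose time axis is average-pooled by
#' `pool_t`.
#'
#' @param recs list of `sz_recording` with state intervals populated.
#' @param low,high,notch filter parameters; see [filter_signal()].
#' @param window_s,overlap windowing parameters; see [segment_windows()].
#' @param scales CWT scales for the ECG scalogram.
#' @param pool_t integer time-pooling factor applied to the scalogram.
#' @return Object of class `szfuse_dataset`: arrays `eeg`
#'   (n x channels x samples), `scal` (n x scales x pooled samples), `ecg`
#'   (n x samples), labels `y` (0/1) and `d` (episode), `n_episodes`, `fs`,
#'   and a `manifest` recording the preprocessing choices.
#' @export
preprocess_patient <- function(recs, low = 0.1, high = 70, notch = c(48, 52),
                               window_s = 1, overlap = 0, scales = 1:32,
                               pool_t = 4L) {
  segs <- lapply(recs, function(rec) {
    filt <- rec
    for (ci in seq_len(nrow(rec$eeg))) {
      filt$eeg[ci, ] <- minmax_normalize(
        filter_signal(rec$eeg[ci, ], rec$fs, low, high, notch))
    }
    filt$ecg <- minmax_normalize(filter_signal(rec$ecg, rec$fs, low, high, notch))
    segment_windows(filt, window_s = window_s, overlap = overlap)
  })
  eeg <- do.call(abind1, lapply(segs, `[[`, "eeg"))
  ecg <- do.call(rbind, lapply(segs, `[[`, "ecg"))
  y <- unlist(lapply(segs, `[[`, "y"))
  d <- unlist(lapply(segs, `[[`, "d"))
  n <- dim(eeg)[1L]
  scal0 <- cwt_scalogram(ecg[1L, ], scales)
  scal0 <- pool_scalogram_time(scal0, pool_t)
  scal <- array(0, c(n, nrow(scal0), ncol(scal0)))
  scal[1L, , ] <- scal0
  if (n > 1L) {
    for (i in 2L:n) {
      scal[i, , ] <- pool_scalogram_time(cwt_scalogram(ecg[i, ], scales), pool_t)
    }
  }
  structure(list(eeg = eeg, scal = scal, ecg = ecg,
                 y = as.integer(y), d = as.integer(d),
                 n_episodes = length(unique(d)), fs = recs[[1L]]$fs,
                 manifest = list(low = low, high = high, notch = notch,
                                 window_s = window_s, overlap = overlap,
                                 scales = range(scales), pool_t = pool_t,
                                 normalization = "per channel per recording, after filtering",
                                 n_segments = n)),
            class = "szfuse_dataset")
}

# rbind for the first axis of 3-d arrays
abind1 <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) dim(p)[1L] > 0L, logical(1))]
  d <- dim(parts[[1L]])
  n <- sum(vapply(parts, function(p) dim(p)[1L], integer(1)))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1L]
    if (k) out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' @export
print.szfuse_dataset <- function(x, ...) {
  cat(sprintf("<szfuse_dataset> %d windows (%d preictal / %d interictal), %d episodes\n",
              length(x$y), sum(x$y == 1L), sum(x$y == 0L), x$n_episodes))
  cat(sprintf("  EEG %d ch x %d samples @ %g Hz; scalogram %d x %d\n",
              dim(x$eeg)[2L], dim(x$eeg)[3L], x$fs,
              dim(x$scal)[2L], dim(x$scal)[3L]))
  invisible(x)
}
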