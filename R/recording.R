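#' Multimodal recording container
#'
#' Bundles a multichannel EEG matrix and a single ECG trace sampled at a
#' common rate, together with half-open, 0-based sample intervals marking
#' interictal and preictal spans and an integer episode identifier.
#'
#' @param eeg numeric matrix, channels x samples.
#' @param ecg numeric vector with as many samples as `eeg` has columns.
#' @param fs sampling rate in Hz.
#' @param episode_id integer episode label, 0-based.
#' @param state_intervals data frame with columns `start`, `end` (half-open,
#'   0-based sample indices) and `state` (`"interictal"` or `"preictal"`),
#'   sorted and pairwise disjoint. May have zero rows.
#' @param metadata free-form named list.
#' @return An object of class `sz_recording`.
#' @export
recording <- function(eeg, ecg, fs, episode_id = 0L,
                      state_intervals = empty_intervals(),
                      metadata = list()) {
  if (!is.matrix(eeg)) stop("recording: 'eeg' must be a channels x samples matrix")
  if (length(ecg) != ncol(eeg)) {
    stop(sprintf("recording: eeg has %d samples but ecg has %d",
                 ncol(eeg), length(ecg)))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("recording: 'fs' must be a positive scalar")
  }
  r <- structure(list(eeg = eeg, ecg = as.numeric(ecg), fs = fs,
                      episode_id = as.integer(episode_id),
                      state_intervals = state_intervals,
                      metadata = metadata),
                 class = "sz_recording")
  validate_recording(r)
  r
}

empty_intervals <- function() {
  data.frame(start = integer(0), end = integer(0), state = character(0),
             stringsAsFactors = FALSE)
}

#' @keywords internal
validate_recording <- function(r) {
  iv <- r$state_intervals
  if (nrow(iv)) {
    if (!all(iv$state %in% c("interictal", "preictal"))) {
      stop("recording: interval states must be 'interictal' or 'preictal'")
    }
    if (any(iv$end <= iv$start)) stop("recording: empty or reversed interval")
    if (any(iv$start < 0) || any(iv$end > ncol(r$eeg))) {
      stop("recording: interval outside the sample range")
    }
    o <- order(iv$start)
    if (!identical(o, seq_len(nrow(iv)))) stop("recording: intervals not sorted")
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)])) {
      stop("recording: overlapping intervals")
    }
  }
  invisible(r)
}

#' @export
print.sz_recording <- function(x, ...) {
  cat(sprintf("<sz_recording> episode %d: %d EEG channels + ECG, %d samples @ %g Hz (%.1f s)\n",
              x$episode_id, nrow(x$eeg), ncol(x$eeg), x$fs, ncol(x$eeg) / x$fs))
  if (nrow(x$state_intervals)) {
    for (i in seq_len(nrow(x$state_intervals))) {
      iv <- x$state_intervals[i, ]
      cat(sprintf("  %-11s [%g s, %g s)\n", iv$state,
                  iv$start / x$fs, iv$end / x$fs))
    }
  } else cat("  (no state intervals)\n")
  invisible(x)
}
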