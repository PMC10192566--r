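#' Dynamic decision-fusion weights from branch error rates
#'
#' Each branch receives the unnormalized weight `w = 1 + arctan((1 - err) /
#' err)` (radians), and the pair is normalized to sum to one, so the branch
#' with the lower validation error rate dominates the fused decision while
#' the weaker branch still contributes. Error rates below `eps` are clamped
#' to `eps` to keep the arctangent argument finite.
#'
#' @param err1,err2 classification error rates of the two branches, in
#'   `[0, 1]`.
#' @param eps positive clamp for vanishing error rates (default `1e-6`).
#' @return Object of class `fusion_weights`: `err1`, `err2`, unnormalized
#'   `w1`, `w2` and normalized `W1`, `W2` (`W1 + W2 == 1`).
#' @export
dynamic_weights <- function(err1, err2, eps = 1e-6) {
  for (nm in c("err1", "err2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("dynamic_weights: %s must be a single error rate in [0, 1]", nm))
    }
  }
  e1 <- max(err1, eps); e2 <- max(err2, eps)
  w1 <- 1 + atan((1 - e1) / e1)
  w2 <- 1 + atan((1 - e2) / e2)
  structure(list(err1 = err1, err2 = err2, w1 = w1, w2 = w2,
                 W1 = w1 / (w1 + w2), W2 = w2 / (w1 + w2)),
            class = "fusion_weights")
}

#' Fixed equal fusion weights
#'
#' The ablation setting in which both branches always weigh 0.5.
#' @return A `fusion_weights` object with `W1 = W2 = 0.5`.
#' @export
fixed_weights <- function() {
  structure(list(err1 = NA_real_, err2 = NA_real_, w1 = 1, w2 = 1,
                 W1 = 0.5, W2 = 0.5), class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights> W1 = %.4f, W2 = %.4f (err1 = %s, err2 = %s)\n",
              x$W1, x$W2, format(x$err1, digits = 4),
              format(x$err2, digits = 4)))
  invisible(x)
}

#' Decision-level fusion of branch probabilities
#'
#' Weighted average of aligned probability batches: `fused = W1 * p_eeg +
#' W2 * p_ecg`. Rows of the result are valid probability vectors. The
#' predicted class is the row argmax; an exact tie goes to class 0
#' (interictal), the conservative no-alarm choice.
#'
#' @param p_eeg,p_ecg probability matrices over the same segments in the
#'   same order (n x classes).
#' @param weights a `fusion_weights` object.
#' @return List with `prob` (fused matrix) and `class` (0-based labels).
#' @export
fuse_decisions <- function(p_eeg, p_ecg, weights) {
  if (!inherits(weights, "fusion_weights")) {
    stop("fuse_decisions: 'weights' must be a fusion_weights object")
  }
  if (!all(dim(p_eeg) == dim(p_ecg))) {
    stop(sprintf("fuse_decisions: misaligned batches (%s vs %s)",
                 paste(dim(p_eeg), collapse = "x"),
                 paste(dim(p_ecg), collapse = "x")))
  }
  fused <- weights$W1 * p_eeg + weights$W2 * p_ecg
  list(prob = fused, class = max.col(fused, ties.method = "first") - 1L)
}

#' Data-level fusion: stack ECG onto the EEG matrix
#'
#' Ablation mode in which the raw ECG trace is appended as an extra row of
#' the EEG window so a single EEG-type branch sees both modalities. The two
#' inputs must share the sampling rate and be time aligned.
#'
#' @param eeg_window channels x samples matrix.
#' @param ecg_window numeric vector of the same sample count.
#' @param fs_eeg,fs_ecg optional sampling rates; if both given they must be
#'   equal.
#' @return `(channels + 1)` x samples matrix, ECG last.
#' @export
fuse_data_level <- function(eeg_window, ecg_window, fs_eeg = NULL, fs_ecg = NULL) {
  if (!is.null(fs_eeg) && !is.null(fs_ecg) && fs_eeg != fs_ecg) {
    stop(sprintf("fuse_data_level: sampling rates differ (%g vs %g Hz)",
                 fs_eeg, fs_ecg))
  }
  if (length(ecg_window) != ncol(eeg_window)) {
    stop(sprintf("fuse_data_level: time misalignment (%d vs %d samples)",
                 ncol(eeg_window), length(ecg_window)))
  }
  rbind(eeg_window, as.numeric(ecg_window))
}

#' Feature-level fusion: concatenate branch features
#'
#' Ablation mode concatenating the EEG feature vector (first) and the ECG
#' feature vector into one feature fed to a single two-layer classifier.
#'
#' @param f_eeg,f_ecg feature vectors, or matrices of row-wise features.
#' @return Concatenated vector or matrix (EEG features first).
#' @export
fuse_feature_level <- function(f_eeg, f_ecg) {
  if (is.matrix(f_eeg) || is.matrix(f_ecg)) {
    if (nrow(f_eeg) != nrow(f_ecg)) {
      stop("fuse_feature_level: batches misaligned")
    }
    return(cbind(f_eeg, f_ecg))
  }
  c(f_eeg, f_ecg)
}
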