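#' Cross-entropy classification loss on fused probabilities
#'
#' Mean negative log probability assigned to the true class, computed on
#' the (already fused) probability rows.
#'
#' @param p_fused n x classes matrix of probability rows.
#' @param y 0-based integer class labels, length n.
#' @return Scalar loss.
#' @export
classifier_loss <- function(p_fused, y) {
  check_prob_rows(p_fused, "classifier_loss")
  if (nrow(p_fused) != length(y)) stop("classifier_loss: labels misaligned")
  ce_from_probs(p_fused, as.integer(y))
}

#' Episode discriminator losses
#'
#' Mean cross-entropy of each discriminator's probability output against the
#' episode labels of the batch (one loss per modality).
#'
#' @param p_d_eeg,p_d_ecg n x K probability matrices emitted by the EEG and
#'   ECG episode discriminators.
#' @param d 0-based episode labels (the training episodes of the fold,
#'   relabeled `0..K-1`).
#' @return List with scalars `L_d_eeg` and `L_d_ecg`.
#' @export
discriminator_losses <- function(p_d_eeg, p_d_ecg, d) {
  check_prob_rows(p_d_eeg, "discriminator_losses")
  check_prob_rows(p_d_ecg, "discriminator_losses")
  d <- as.integer(d)
  list(L_d_eeg = ce_from_probs(p_d_eeg, d),
       L_d_ecg = ce_from_probs(p_d_ecg, d))
}

#' Joint adversarial objective
#'
#' `L_sum = L_c - lambda * (L_d_eeg + L_d_ecg)`: the classifier and feature
#' extractors minimize it while the reversed gradient lets the episode
#' discriminators improve, driving features toward episode invariance.
#' `lambda = 0` removes the adversarial term (the non-adversarial ablation).
#'
#' @param L_c classifier loss.
#' @param L_d_eeg,L_d_ecg discriminator losses.
#' @param lambda nonnegative adversarial trade-off (default 0.1).
#' @return Scalar.
#' @export
total_loss <- function(L_c, L_d_eeg, L_d_ecg, lambda = 0.1) {
  if (lambda < 0) stop("total_loss: lambda must be >= 0")
  L_c - lambda * (L_d_eeg + L_d_ecg)
}

check_prob_rows <- function(p, where, tol = 1e-6) {
  if (!is.matrix(p)) stop(sprintf("%s: expected a probability matrix", where))
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > 1e-4)) {
    stop(sprintf("%s: rows must be probability vectors", where))
  }
  invisible(p)
}
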