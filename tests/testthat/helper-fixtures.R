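# Shared fixtures: everything is generated in code at test time.

# Small synthetic patient preprocessed once and memoized across test files.
.fixture_env <- new.env()

quick_dataset <- function(eeg_effect = 0.8, ecg_effect = 0.8, shift = 1,
                          seed = 1, n_episodes = 3, seg_s = 40) {
  key <- paste("ds", eeg_effect, ecg_effect, shift, seed, n_episodes, seg_s,
               sep = "_")
  if (is.null(.fixture_env[[key]])) {
    recs <- generate_patient(synthetic_spec(
      n_episodes = n_episodes, seg_seconds_per_state = seg_s,
      episode_shift = shift, eeg_effect = eeg_effect,
      ecg_effect = ecg_effect, seed = seed))
    .fixture_env[[key]] <- preprocess_patient(recs, low = 0.5, high = 28,
                                              notch = NULL)
  }
  .fixture_env[[key]]
}

# Central-difference numerical gradient of a scalar function of an array.
num_grad <- function(fun, x, eps = 1e-5) {
  g <- if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fun(xp) - fun(xm)) / (2 * eps)
  }
  g
}

# Aggregate band power of a multichannel window (channels x samples).
band_power <- function(w, fs, lo, hi) {
  p <- 0
  for (ci in seq_len(nrow(w))) {
    sp <- Mod(stats::fft(w[ci, ] - mean(w[ci, ])))^2
    fr <- (seq_along(sp) - 1) * fs / length(sp)
    p <- p + sum(sp[fr >= lo & fr <= hi])
  }
  p
}

rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

branch_accuracy <- function(run, which = c("eeg", "ecg", "fused")) {
  which <- match.arg(which)
  mean(unlist(lapply(run$predictions, function(q) {
    pred <- switch(which,
                   fused = q$class,
                   eeg = max.col(q$prob_eeg, "first") - 1L,
                   ecg = max.col(q$prob_ecg, "first") - 1L)
    pred == q$y
  })))
}

# Episode-probe accuracy on frozen EEG features: a freshly trained
# multinomial classifier (independent of the package's discriminators),
# evaluated on a held-out half of the training segments, averaged over folds.
probe_episode_accuracy <- function(run, ds) {
  mean(vapply(seq_along(run$fits), function(k) {
    fit <- run$fits[[k]]
    tr <- which(ds$d %in% fit$train_episodes)
    f <- extract_features(fit, ds, tr, "eeg")
    dd <- factor(ds$d[tr])
    half <- sample(length(tr), length(tr) %/% 2)
    m <- nnet::multinom(dd[half] ~ ., data = data.frame(f[half, ]),
                        trace = FALSE, maxit = 200)
    mean(stats::predict(m, newdata = data.frame(f[-half, ])) == dd[-half])
  }, numeric(1)))
}
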