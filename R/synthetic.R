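#' Specification for a synthetic multimodal patient
#'
#' Describes the statistical structure of a simulated patient: the number of
#' seizure episodes, the duration of the interictal and preictal block in
#' each episode, and scalars controlling between-episode distribution shift
#' and the class signal carried by each modality.
#'
#' The generator produces, per episode, one contiguous interictal block
#' followed by one preictal block. EEG channels are band-limited Gaussian
#' noise plus a shared 16 Hz background rhythm whose amplitude drifts
#' mildly across episodes with `episode_shift`. The preictal signature has
#' two parts: an episode-stable narrow-band 5 Hz marker with amplitude
#' `eeg_effect`, and an episode-bound rhythm (amplitude
#' `2.5 * eeg_effect * min(1, episode_shift)`) whose centre frequency moves
#' with the episode index (8, 10, 12 Hz at `episode_shift = 1`) and whose
#' class association is unstable — it accompanies preictal spans in all but
#' the last episode, where it occurs during the interictal baseline
#' instead. The preictal state is therefore expressed differently in every
#' episode: a classifier that treats the episode-bound rhythm as a preictal
#' marker misreads the episode where the association flips, while
#' episode-invariant features are unaffected. ECG is a Gaussian-bump pulse
#' train whose mean inter-beat interval shortens during preictal spans in
#' proportion to `ecg_effect`, with multiplicative jitter scaled by
#' `noise_sd`.
#'
#' @param n_episodes number of episodes (>= 1; the leave-one-episode-out
#'   protocol additionally requires >= 3).
#' @param seg_seconds_per_state seconds of interictal and of preictal data in
#'   each episode.
#' @param fs sampling rate, Hz.
#' @param n_eeg_channels number of EEG channels.
#' @param episode_shift nonnegative scalar; 0 means episodes are identically
#'   distributed.
#' @param eeg_effect nonnegative amplitude of the stable preictal 5 Hz EEG
#'   marker, in units of the background noise standard deviation; also
#'   scales the episode-bound rhythm.
#' @param ecg_effect nonnegative scalar; the preictal inter-beat interval is
#'   shortened by a factor `1 - 0.2 * ecg_effect` (floored at 0.35).
#' @param noise_sd nonnegative noise scale for both modalities.
#' @param seed integer seed; identical specs give byte-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_episodes = 3L, seg_seconds_per_state = 60,
                           fs = 64, n_eeg_channels = 8L,
                           episode_shift = 1, eeg_effect = 0.8,
                           ecg_effect = 0.8, noise_sd = 1, seed = 1L) {
  spec <- list(n_episodes = as.integer(n_episodes),
               seg_seconds_per_state = seg_seconds_per_state,
               fs = fs, n_eeg_channels = as.integer(n_eeg_channels),
               episode_shift = episode_shift, eeg_effect = eeg_effect,
               ecg_effect = ecg_effect, noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

#' @keywords internal
validate_synthetic_spec <- function(spec) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("synthetic_spec: field '%s' %s", field, msg),
                    call. = FALSE)
  }
  chk(length(spec$n_episodes) == 1L && !is.na(spec$n_episodes) &&
        spec$n_episodes >= 1L, "n_episodes", "must be >= 1")
  chk(is.numeric(spec$fs) && spec$fs > 0, "fs", "must be > 0")
  chk(is.numeric(spec$seg_seconds_per_state) && spec$seg_seconds_per_state > 0,
      "seg_seconds_per_state", "must be > 0")
  chk(spec$n_eeg_channels >= 1L, "n_eeg_channels", "must be >= 1")
  for (f in c("episode_shift", "eeg_effect", "ecg_effect", "noise_sd")) {
    chk(is.numeric(spec[[f]]) && length(spec[[f]]) == 1L && spec[[f]] >= 0,
        f, "must be a nonnegative scalar")
  }
  chk(length(spec$seed) == 1L && !is.na(spec$seed), "seed",
      "must be a single integer")
  invisible(spec)
}

# Band-pass filtered unit-variance Gaussian noise centred on f0.
narrowband_noise <- function(n, fs, f0, bw = 3) {
  ny <- fs / 2
  lo <- max(0.01, (f0 - bw / 2) / ny)
  hi <- min(0.99, (f0 + bw / 2) / ny)
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Band-limited broadband background noise, unit variance.
broadband_noise <- function(n, fs, high = 30) {
  ny <- fs / 2
  w <- min(0.95, high / ny)
  bf <- signal::butter(4, w, type = "low")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

episode_seed <- function(seed, ep) {
  (abs(seed) * 10007L + 7919L * ep) %% 2147483629L
}

#' Generate a synthetic multimodal patient
#'
#' Produces one [recording()] per episode according to a [synthetic_spec()].
#' Each episode draws from its own RNG substream derived from `spec$seed`,
#' so extending `n_episodes` leaves earlier episodes unchanged and identical
#' specs yield identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return List of `sz_recording`, one per episode, episode ids `0..N-1`.
#' @export
generate_patient <- function(spec) {
  validate_synthetic_spec(spec)
  lapply(seq_len(spec$n_episodes) - 1L, function(ep) generate_episode(spec, ep))
}

generate_episode <- function(spec, ep) {
  fs <- spec$fs
  ns <- round(spec$seg_seconds_per_state * fs)   # samples per state block
  total <- 2L * ns
  C <- spec$n_eeg_channels
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(episode_seed(spec$seed, ep))

  # deterministic channel weights (identical across episodes); the stable
  # cue and the episode-varying component live on distinct channel groups.
  ch <- seq_len(C)
  w_bg  <- 0.6 + 0.4 * cos(2 * pi * ch / C)
  w_cue <- 0.6 + 0.4 * sin(2 * pi * ch / C)
  w_var <- numeric(C); w_var[min(3L, C):min(4L, C)] <- 1

  # Episode structure. The preictal signature has two parts:
  #   (a) an episode-stable narrow-band 5 Hz component, amplitude
  #       eeg_effect — the reliable marker;
  #   (b) an episode-bound rhythm near 10 Hz whose centre frequency moves
  #       with the episode index (8, 10, 12 Hz at episode_shift = 1) and
  #       whose class association is NOT stable: it accompanies preictal
  #       spans in all but the last episode, where it occurs during the
  #       interictal baseline instead.
  # The frequency signature makes the episode-bound rhythm strongly
  # episode-discriminative (it survives per-channel min-max normalization),
  # so episode-invariance pressure suppresses sensitivity to it; a model
  # without that pressure can treat it as a preictal marker — consistent
  # across its training episodes — and misreads the episode where the
  # association flips. Both components vanish when eeg_effect or (for b)
  # episode_shift is 0. A mild amplitude drift of the shared background
  # rhythm keeps all episode pairs marginally distinguishable.
  amp_e <- 1 + 0.15 * spec$episode_shift * ep
  a_eb <- 2.5 * spec$eeg_effect * min(1, spec$episode_shift)
  f_eb <- 8 + 2 * ep * spec$episode_shift
  preictal <- c(rep(0, ns), rep(1, ns))
  ebmask <- if (ep < spec$n_episodes - 1L) preictal else 1 - preictal

  rho <- narrowband_noise(total, fs, f0 = 16)    # shared background rhythm
  cue <- narrowband_noise(total, fs, f0 = 5)     # stable preictal marker
  vcmp <- narrowband_noise(total, fs, f0 = f_eb, bw = 1.5)  # episode-bound
  eeg <- matrix(0, C, total)
  for (c_i in ch) {
    base <- spec$noise_sd * broadband_noise(total, fs)
    eeg[c_i, ] <- base + amp_e * w_bg[c_i] * rho +
      spec$eeg_effect * w_cue[c_i] * (cue * preictal) +
      a_eb * w_var[c_i] * (vcmp * ebmask)
  }

  ecg <- generate_ecg(spec, ep, ns, fs)

  iv <- data.frame(start = c(0L, ns), end = c(ns, total),
                   state = c("interictal", "preictal"),
                   stringsAsFactors = FALSE)
  recording(eeg, ecg, fs, episode_id = ep, state_intervals = iv,
            metadata = list(generator = "seizefuse-synthetic",
                            episode_shift = spec$episode_shift,
                            eeg_effect = spec$eeg_effect,
                            ecg_effect = spec$ecg_effect,
                            seed = spec$seed))
}

# Quasi-periodic Gaussian-bump pulse train; preictal beats come faster.
generate_ecg <- function(spec, ep, ns, fs) {
  total <- 2L * ns
  dur <- total / fs
  rr_base <- 0.8 * (1 + 0.05 * spec$episode_shift * ep)
  rr_pre <- rr_base * max(0.35, 1 - 0.2 * spec$ecg_effect)
  t_beat <- numeric(0)
  t <- stats::runif(1, 0, 0.5)
  while (t < dur) {
    t_beat <- c(t_beat, t)
    rr <- if (t >= ns / fs) rr_pre else rr_base
    jit <- 1 + 0.05 * spec$noise_sd * stats::rnorm(1)
    t <- t + max(0.25, rr * jit)
  }
  tt <- (seq_len(total) - 1) / fs
  x <- numeric(total)
  width <- 0.04
  for (tb in t_beat) {
    lo <- max(1L, floor((tb - 4 * width) * fs))
    hi <- min(total, ceiling((tb + 4 * width) * fs))
    sel <- lo:hi
    x[sel] <- x[sel] + exp(-(tt[sel] - tb)^2 / (2 * width^2))
  }
  x + 0.05 * spec$noise_sd * stats::rnorm(total)
}
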