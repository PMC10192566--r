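# Minimal European Data Format (EDF) I/O: fixed 256-byte header plus
# 256 bytes per signal, 16-bit little-endian samples, 1-second data records.
# Covers what the pipeline needs (uniform rate, standard header); EDF+
# annotations are not parsed — seizure times come from a JSON/CSV sidecar.

pad_field <- function(x, width) {
  s <- sprintf("%-*s", width, as.character(x))
  substr(s, 1L, width)
}

num_field <- function(x, width) {
  s <- formatC(x, digits = width - 2L, width = 1, format = "g")
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_field(s, width)
}

#' Write a multichannel signal matrix as EDF
#'
#' @param path output file.
#' @param signals numeric matrix, channels x samples; the sample count must
#'   be a multiple of `fs` (whole 1-second records).
#' @param fs sampling rate (identical for every channel), Hz.
#' @param labels channel labels (<= 16 ASCII chars each).
#' @param start POSIXct start time stamped into the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, labels = NULL,
                      start = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1L)
  nsig <- nrow(signals)
  nsamp <- ncol(signals)
  if (nsamp %% fs != 0) stop("write_edf: sample count must be a whole number of 1-s records")
  nrec <- nsamp %/% fs
  if (is.null(labels)) labels <- sprintf("Sig%d", seq_len(nsig))

  pmin <- apply(signals, 1L, min)
  pmax <- apply(signals, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8L))
  wr(pad_field("X X X X", 80L))
  wr(pad_field("Startdate X X X X", 80L))
  wr(pad_field(format(start, "%d.%m.%y"), 8L))
  wr(pad_field(format(start, "%H.%M.%S"), 8L))
  wr(pad_field(256L * (nsig + 1L), 8L))
  wr(pad_field("", 44L))
  wr(pad_field(nrec, 8L))
  wr(pad_field("1", 8L))
  wr(pad_field(nsig, 4L))
  for (f in list(list(labels, 16L),
                 list(rep("", nsig), 80L),
                 list(rep("uV", nsig), 8L))) {
    for (i in seq_len(nsig)) wr(pad_field(f[[1L]][i], f[[2L]]))
  }
  for (i in seq_len(nsig)) wr(num_field(pmin[i], 8L))
  for (i in seq_len(nsig)) wr(num_field(pmax[i], 8L))
  for (i in seq_len(nsig)) wr(pad_field(dmin, 8L))
  for (i in seq_len(nsig)) wr(pad_field(dmax, 8L))
  for (i in seq_len(nsig)) wr(pad_field("", 80L))
  for (i in seq_len(nsig)) wr(pad_field(fs, 8L))
  for (i in seq_len(nsig)) wr(pad_field("", 32L))

  # re-read the printed physical range so reader and writer agree exactly
  pmin_h <- vapply(pmin, function(v) as.numeric(num_field(v, 8L)), numeric(1))
  pmax_h <- vapply(pmax, function(v) as.numeric(num_field(v, 8L)), numeric(1))
  scale <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(nrec)) {
    sel <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nsig)) {
      dig <- round((signals[i, sel] - pmin_h[i]) * scale[i] + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file with a uniform sampling rate across channels.
#' @return List with `signals` (channels x samples matrix, physical units),
#'   `fs`, `labels`, `n_records`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_edf: no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L)                     # version
  rd(160L)                   # patient + recording id
  rd(16L)                    # date + time
  rd(8L)                     # header bytes
  rd(44L)
  nrec <- as.integer(rd(8L))
  recdur <- as.numeric(rd(8L))
  nsig <- as.integer(rd(4L))
  fld <- function(w) vapply(seq_len(nsig), function(i) rd(w), character(1))
  labels <- trimws(fld(16L))
  fld(80L); fld(8L)
  pmin <- as.numeric(fld(8L)); pmax <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L))  # samples per record
  fld(32L)
  if (length(unique(spr)) != 1L) {
    stop("read_edf: channels disagree on samples per record (mixed rates)")
  }
  fs <- spr[1L] / recdur
  total <- nrec * spr[1L]
  signals <- matrix(0, nsig, total)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    sel <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (i in seq_len(nsig)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little", signed = TRUE)
      signals[i, sel] <- (dig - dmin[i]) * scale[i] + pmin[i]
    }
  }
  list(signals = signals, fs = fs, labels = labels, n_records = nrec)
}

#' Seizure annotations and channel roles
#'
#' @param seizure_onsets strictly increasing onset times, seconds from the
#'   record start.
#' @param seizure_offsets matching offsets, `offsets[i] > onsets[i]`.
#' @param channel_roles named character vector mapping channel label to
#'   `"eeg"`, `"ecg"` or `"drop"`; exactly one `"ecg"` channel is kept.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(seizure_onsets, seizure_offsets, channel_roles) {
  if (length(seizure_onsets) != length(seizure_offsets)) {
    stop("annotation_set: onsets and offsets differ in length")
  }
  if (length(seizure_onsets) > 1L && any(diff(seizure_onsets) <= 0)) {
    stop("annotation_set: seizure onsets must be strictly increasing")
  }
  if (any(seizure_offsets <= seizure_onsets)) {
    stop("annotation_set: each offset must exceed its onset")
  }
  roles <- as.character(channel_roles)
  if (!all(roles %in% c("eeg", "ecg", "drop"))) {
    stop("annotation_set: roles must be 'eeg', 'ecg' or 'drop'")
  }
  if (sum(roles == "eeg") < 1L || sum(roles == "ecg") != 1L) {
    stop("annotation_set: need at least one 'eeg' channel and exactly one 'ecg'")
  }
  structure(list(seizure_onsets = as.numeric(seizure_onsets),
                 seizure_offsets = as.numeric(seizure_offsets),
                 channel_roles = stats::setNames(roles, names(channel_roles))),
            class = "annotation_set")
}

#' Load a recording from EDF with channel selection
#'
#' EEG channels are returned in the order they appear in
#' `annotations$channel_roles`; channels marked `"drop"` are excluded.
#'
#' @param edf_path path to the EDF file.
#' @param annotations an [annotation_set()].
#' @param episode_id episode label to stamp on the recording.
#' @return An `sz_recording` (state intervals not yet populated; see
#'   [extract_state_intervals()]).
#' @export
load_recording <- function(edf_path, annotations, episode_id = 0L) {
  e <- read_edf(edf_path)
  roles <- annotations$channel_roles
  missing <- setdiff(names(roles), e$labels)
  if (length(missing)) {
    stop(sprintf("load_recording: channel(s) not present in %s: %s",
                 basename(edf_path), paste(missing, collapse = ", ")))
  }
  eeg_names <- names(roles)[roles == "eeg"]
  ecg_name <- names(roles)[roles == "ecg"]
  eeg <- e$signals[match(eeg_names, e$labels), , drop = FALSE]
  ecg <- e$signals[match(ecg_name, e$labels), ]
  recording(eeg, ecg, e$fs, episode_id = episode_id,
            metadata = list(path = edf_path, labels = eeg_names,
                            ecg_label = ecg_name))
}

#' Cut preictal and interictal intervals around annotated seizures
#'
#' For each seizure onset `t` the preictal interval is `[t - preictal_s, t)`;
#' an onset closer than `preictal_s` to the record start is skipped with a
#' warning. Interictal intervals are the maximal spans lying at least
#' `interictal_gap_s` away from every seizure and every preictal span (a
#' postictal exclusion of the same length follows each offset); spans shorter
#' than `min_interictal_s` are discarded.
#'
#' @param rec an `sz_recording`.
#' @param annotations an [annotation_set()].
#' @param preictal_s preictal window length, seconds (default 300).
#' @param min_interictal_s minimum retained interictal span, seconds.
#' @param interictal_gap_s guard gap between interictal data and any seizure
#'   or preictal span, seconds.
#' @return The recording with `state_intervals` populated; the number of
#'   skipped onsets is recorded in `metadata$skipped_onsets`.
#' @export
extract_state_intervals <- function(rec, annotations, preictal_s = 300,
                                    min_interictal_s = 300,
                                    interictal_gap_s = 1800) {
  if (preictal_s <= 0) stop("extract_state_intervals: preictal_s must be > 0")
  fs <- rec$fs
  total_s <- ncol(rec$eeg) / fs
  onsets <- annotations$seizure_onsets
  offsets <- annotations$seizure_offsets
  keep <- onsets - preictal_s >= 0
  skipped <- sum(!keep)
  if (skipped) {
    warning(sprintf("%d seizure(s) skipped: preictal window would start before the record", skipped))
  }
  pre <- data.frame(start = onsets[keep] - preictal_s, end = onsets[keep],
                    state = rep("preictal", sum(keep)),
                    stringsAsFactors = FALSE)

  # blocked spans for interictal selection (seconds)
  blk_lo <- pmin(onsets - preictal_s, onsets) - interictal_gap_s
  blk_hi <- offsets + interictal_gap_s
  free <- data.frame(lo = 0, hi = total_s)
  for (i in seq_along(blk_lo)) {
    nxt <- list()
    for (j in seq_len(nrow(free))) {
      lo <- free$lo[j]; hi <- free$hi[j]
      if (blk_hi[i] <= lo || blk_lo[i] >= hi) {
        nxt[[length(nxt) + 1L]] <- c(lo, hi)
      } else {
        if (blk_lo[i] > lo) nxt[[length(nxt) + 1L]] <- c(lo, blk_lo[i])
        if (blk_hi[i] < hi) nxt[[length(nxt) + 1L]] <- c(blk_hi[i], hi)
      }
    }
    free <- if (length(nxt)) as.data.frame(do.call(rbind, nxt)) else
      data.frame(lo = numeric(0), hi = numeric(0))
    names(free) <- c("lo", "hi")
  }
  free <- free[free$hi - free$lo >= min_interictal_s, , drop = FALSE]
  inter <- data.frame(start = free$lo, end = free$hi,
                      state = rep("interictal", nrow(free)),
                      stringsAsFactors = FALSE)
  iv <- rbind(inter, pre)
  iv <- iv[order(iv$start), , drop = FALSE]
  iv$start <- as.integer(round(iv$start * fs))
  iv$end <- as.integer(round(iv$end * fs))
  iv <- iv[iv$end > iv$start, , drop = FALSE]
  rownames(iv) <- NULL
  rec$state_intervals <- iv
  rec$metadata$skipped_onsets <- skipped
  validate_recording(rec)
  rec
}

#' Persist recordings as EDF plus a JSON sidecar
#'
#' One EDF per episode (`episode_<k>.edf`) with channels `EEG1..EEGn, ECG`,
#' and `episode_<k>.json` listing the state intervals and channel roles, so
#' synthetic data exercises the same reader as real data.
#'
#' @param recs list of `sz_recording`.
#' @param dir output directory (created if needed).
#' @return Character vector of EDF paths, invisibly.
#' @export
write_recordings <- function(recs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in recs) {
    labels <- c(sprintf("EEG%d", seq_len(nrow(r$eeg))), "ECG")
    p <- file.path(dir, sprintf("episode_%d.edf", r$episode_id))
    write_edf(p, rbind(r$eeg, r$ecg), r$fs, labels)
    sidecar <- list(episode_id = r$episode_id, fs = r$fs,
                    channel_roles = as.list(
                      c(stats::setNames(rep("eeg", nrow(r$eeg)),
                                        labels[-length(labels)]),
                        ECG = "ecg")),
                    state_intervals = r$state_intervals)
    jsonlite::write_json(sidecar, sub("\\.edf$", ".json", p),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a directory written by [write_recordings()]
#'
#' @param dir directory containing `episode_<k>.edf` / `.json` pairs.
#' @return List of `sz_recording` ordered by episode id.
#' @export
read_patient_dir <- function(dir) {
  jsons <- sort(list.files(dir, pattern = "^episode_\\d+\\.json$",
                           full.names = TRUE))
  if (!length(jsons)) stop(sprintf("read_patient_dir: no episode sidecars in %s", dir))
  recs <- lapply(jsons, function(j) {
    side <- jsonlite::read_json(j, simplifyVector = TRUE)
    roles <- unlist(side$channel_roles)
    ann <- annotation_set(numeric(0), numeric(0), roles)
    rec <- load_recording(sub("\\.json$", ".edf", j), ann,
                          episode_id = side$episode_id)
    iv <- as.data.frame(side$state_intervals)
    iv$start <- as.integer(iv$start); iv$end <- as.integer(iv$end)
    rec$state_intervals <- iv
    validate_recording(rec)
    rec
  })
  recs[order(vapply(recs, function(r) r$episode_id, integer(1)))]
}
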