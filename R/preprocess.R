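#' Artifact rejection criteria
#'
#' Thresholds for epoch rejection: blinks are VEOG peak-to-peak
#' deflections exceeding `veog_threshold_uv` within any sliding window of
#' `veog_window_ms`; eye movements are HEOG deflections exceeding
#' `heog_threshold_uv` within `heog_window_ms`; any EEG sample beyond
#' `absolute_limit_uv` in magnitude rejects the epoch outright.
#' Comparisons are strict (`>`). Subjects whose epoch rejection rate
#' reaches `subject_exclusion_rate` are excluded from group analysis.
#'
#' @param veog_threshold_uv,heog_threshold_uv,absolute_limit_uv Thresholds
#'   in microvolts (all > 0).
#' @param veog_window_ms,heog_window_ms Sliding-window lengths in ms.
#' @param subject_exclusion_rate Rejection-rate cutoff in (0, 1].
#' @return An object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(veog_threshold_uv = 50, veog_window_ms = 150,
                               heog_threshold_uv = 35, heog_window_ms = 300,
                               absolute_limit_uv = 100,
                               subject_exclusion_rate = 0.30) {
  stopifnot(veog_threshold_uv > 0, heog_threshold_uv > 0,
            absolute_limit_uv > 0, veog_window_ms > 0, heog_window_ms > 0,
            subject_exclusion_rate > 0, subject_exclusion_rate <= 1)
  structure(list(veog_threshold_uv = veog_threshold_uv,
                 veog_window_ms = veog_window_ms,
                 heog_threshold_uv = heog_threshold_uv,
                 heog_window_ms = heog_window_ms,
                 absolute_limit_uv = absolute_limit_uv,
                 subject_exclusion_rate = subject_exclusion_rate),
            class = "rejection_criteria")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth high-pass at `low_hz` followed by a
#' 4th-order Butterworth low-pass at `high_hz`, each run forward and
#' backward (`signal::filtfilt`) so the net filter is zero-phase.
#' Cut-offs are the -3 dB points of each single pass.
#'
#' @param x Numeric vector, or matrix with one channel per column.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order of each section.
#' @return Filtered signal, same shape as `x`.
#' @examples
#' fs <- 512; t <- seq(0, 2, by = 1/fs)
#' x <- 10 + sin(2 * pi * 5 * t) # DC offset + 5 Hz
#' y <- bandpass_filter(x, 0.1, 30, fs)
#' @export
bandpass_filter <- function(x, low_hz, high_hz, fs, order = 4) {
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < Nyquist (", fs / 2, " Hz)")
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  run <- function(v) signal::filtfilt(lp, signal::filtfilt(hp, v))
  if (is.matrix(x)) apply(x, 2, run) else run(as.numeric(x))
}

#' Re-reference EEG channels to the averaged mastoids
#'
#' Subtracts `(M1 + M2) / 2` sample-wise from every EEG channel. EOG and
#' mastoid channels are left untouched.
#'
#' @param recording An `eeg_recording` containing channels M1 and M2.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(recording) {
  if (!all(MASTOIDS %in% colnames(recording$data)))
    stop("mastoid channels M1/M2 missing; cannot re-reference")
  ref <- (recording$data[, "M1"] + recording$data[, "M2"]) / 2
  recording$data[, EEG_CHANNELS] <- recording$data[, EEG_CHANNELS] - ref
  recording
}

#' Filter an entire recording with EEG and EOG pass-bands
#'
#' EEG channels get the 0.1--30 Hz band, EOG channels 0.1--10 Hz
#' (both zero-phase Butterworth, see [bandpass_filter()]). Mastoids are
#' filtered with the EEG band.
#'
#' @param recording An `eeg_recording`.
#' @param eeg_band,eog_band Length-2 numeric band edges in Hz.
#' @return The filtered `eeg_recording`.
#' @export
filter_recording <- function(recording, eeg_band = c(0.1, 30),
                             eog_band = c(0.1, 10)) {
  fs <- recording$fs
  eeg <- c(EEG_CHANNELS, MASTOIDS)
  recording$data[, eeg] <-
    bandpass_filter(recording$data[, eeg], eeg_band[1], eeg_band[2], fs)
  recording$data[, EOG_CHANNELS] <-
    bandpass_filter(recording$data[, EOG_CHANNELS], eog_band[1], eog_band[2], fs)
  recording
}

#' Epoch a recording around events and baseline-correct
#'
#' Cuts fixed-length windows (default -200 to +800 ms, half-open
#' `[-200, 800)`, with t = 0 at the event sample) around all events of the
#' requested kind, and subtracts the per-channel mean of the pre-stimulus
#' baseline `[-200, 0)` from every epoch. Events whose windows overlap a
#' recording edge are dropped with a warning rather than zero-padded.
#'
#' @param recording An `eeg_recording`.
#' @param lock Event kind to lock to: `"cue"` or `"flash"`.
#' @param window_ms Length-2 epoch window in ms relative to the event.
#' @param baseline Logical; subtract the pre-stimulus mean?
#' @return An `epoch_set`: list with `data` (array epoch x channel x
#'   sample), `channels`, `fs`, `times` (seconds relative to the event),
#'   `lock`, and `info` (one row per epoch: event metadata plus `kept` and
#'   `reason`).
#' @export
epoch_recording <- function(recording, lock = c("cue", "flash"),
                            window_ms = c(-200, 800), baseline = TRUE) {
  lock <- match.arg(lock)
  fs <- recording$fs
  n_pre <- round(-window_ms[1] / 1000 * fs)
  n_total <- round(diff(window_ms) / 1000 * fs)
  stopifnot(n_total > 0, n_pre >= 0, n_pre < n_total)
  ev <- recording$events[recording$events$kind == lock, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events of kind '", lock, "'")
  first <- ev$sample - n_pre
  last <- first + n_total - 1L
  ok <- first >= 1 & last <= nrow(recording$data)
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  ev <- ev[ok, , drop = FALSE]
  n_ep <- nrow(ev)
  n_ch <- length(recording$channels)
  data <- array(0, c(n_ep, n_ch, n_total),
                dimnames = list(NULL, recording$channels, NULL))
  for (i in seq_len(n_ep))
    data[i, , ] <- t(recording$data[seq.int(ev$sample[i] - n_pre,
                                            length.out = n_total), ])
  if (baseline && n_pre > 0) {
    bl <- apply(data[, , seq_len(n_pre), drop = FALSE], c(1, 2), mean)
    data <- data - array(bl, c(n_ep, n_ch, n_total))
  }
  info <- cbind(epoch = seq_len(n_ep), ev,
                kept = TRUE, reason = NA_character_)
  rownames(info) <- NULL
  structure(list(data = data, channels = recording$channels, fs = fs,
                 times = (seq_len(n_total) - 1 - n_pre) / fs,
                 lock = lock, info = info),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set (", x$lock, "-locked): ", dim(x$data)[1], " epochs x ",
      dim(x$data)[2], " channels x ", dim(x$data)[3], " samples @ ",
      x$fs, " Hz\n", sep = "")
  cat("  kept:", sum(x$info$kept), "/", nrow(x$info), "\n")
  invisible(x)
}

# Maximum peak-to-peak (max - min) over all sliding windows of w samples,
# stepped one sample at a time.
sliding_p2p_max <- function(x, w) {
  n <- length(x)
  if (w >= n) return(diff(range(x)))
  hi <- x[seq_len(n - w + 1)]
  lo <- hi
  for (j in seq_len(w - 1)) {
    seg <- x[seq.int(1 + j, n - w + 1 + j)]
    hi <- pmax(hi, seg)
    lo <- pmin(lo, seg)
  }
  max(hi - lo)
}

#' Flag epochs containing ocular or amplitude artifacts
#'
#' Marks an epoch rejected when (checked in this order) the VEOG
#' peak-to-peak deflection within any sliding `veog_window_ms` window
#' exceeds `veog_threshold_uv` (reason `"blink"`), the HEOG deflection
#' within any `heog_window_ms` window exceeds `heog_threshold_uv`
#' (reason `"eye movement"`), or any EEG sample exceeds the absolute
#' limit in magnitude (reason `"absolute limit"`). The absolute rule
#' applies to the EEG channels only, not EOG. All comparisons are strict.
#'
#' @param epochs An `epoch_set` containing HEOG and VEOG channels.
#' @param criteria A [rejection_criteria()].
#' @return The `epoch_set` with updated `info$kept` and `info$reason`.
#' @export
reject_artifacts <- function(epochs, criteria = rejection_criteria()) {
  if (!all(EOG_CHANNELS %in% epochs$channels))
    stop("epochs lack HEOG/VEOG channels")
  fs <- epochs$fs
  wv <- round(criteria$veog_window_ms / 1000 * fs)
  wh <- round(criteria$heog_window_ms / 1000 * fs)
  eeg <- intersect(EEG_CHANNELS, epochs$channels)
  for (i in seq_len(nrow(epochs$info))) {
    veog <- epochs$data[i, "VEOG", ]
    heog <- epochs$data[i, "HEOG", ]
    reason <- NA_character_
    # cheap global-range screen before the sliding scan
    if (diff(range(veog)) > criteria$veog_threshold_uv &&
        sliding_p2p_max(veog, wv) > criteria$veog_threshold_uv) {
      reason <- "blink"
    } else if (diff(range(heog)) > criteria$heog_threshold_uv &&
               sliding_p2p_max(heog, wh) > criteria$heog_threshold_uv) {
      reason <- "eye movement"
    } else if (max(abs(epochs$data[i, eeg, ])) > criteria$absolute_limit_uv) {
      reason <- "absolute limit"
    }
    if (!is.na(reason)) {
      epochs$info$kept[i] <- FALSE
      epochs$info$reason[i] <- reason
    }
  }
  epochs
}

#' Subject exclusion by epoch rejection rate
#'
#' Removes subjects whose rejection rate reaches the criterion
#' (`rate >= subject_exclusion_rate`), logging each removal.
#'
#' @param rates Named numeric vector of per-subject rejection rates in
#'   `[0, 1]`.
#' @param criteria A [rejection_criteria()].
#' @return Names (or indices, if unnamed) of the retained subjects.
#' @examples
#' exclude_subjects(c(s1 = 0.05, s2 = 0.10, s3 = 0.30))
#' @export
exclude_subjects <- function(rates, criteria = rejection_criteria()) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (is.null(names(rates))) names(rates) <- seq_along(rates)
  drop <- rates >= criteria$subject_exclusion_rate
  if (all(drop))
    stop("all subjects exceed the exclusion rate; cannot proceed")
  for (s in names(rates)[drop])
    message("excluding subject ", s, " (rejection rate ",
            round(rates[[s]] * 100), "%)")
  names(rates)[!drop]
}

#' Rejection rate of an epoch set
#' @param epochs An `epoch_set`.
#' @return Fraction of epochs flagged rejected.
#' @export
rejection_rate <- function(epochs) mean(!epochs$info$kept)

#' Full single-subject preprocessing chain
#'
#' Re-references to averaged mastoids, band-pass filters (EEG 0.1--30 Hz,
#' EOG 0.1--10 Hz), epochs around cue and flash events (-200 to +800 ms,
#' baseline `[-200, 0)`), and flags artifact epochs.
#'
#' @param recording An `eeg_recording`.
#' @param criteria A [rejection_criteria()].
#' @return List with `cue` and `target` `epoch_set`s (flash-locked epochs
#'   under `target`) and the combined `rejection_rate`.
#' @export
preprocess_subject <- function(recording, criteria = rejection_criteria()) {
  rec <- filter_recording(rereference(recording))
  cue <- reject_artifacts(epoch_recording(rec, "cue"), criteria)
  target <- reject_artifacts(epoch_recording(rec, "flash"), criteria)
  list(cue = cue, target = target,
       rejection_rate = mean(!c(cue$info$kept, target$info$kept)))
}
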