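#' @keywords internal
"_PACKAGE"

# Channel layout of the synthetic montage. The first six are the posterior
# EEG pairs used for lateralized features; HEOG/VEOG monitor eye activity;
# M1/M2 are the mastoid references.
EEG_CHANNELS <- c("PO7", "PO8", "O1", "O2", "PO3", "PO4")
EOG_CHANNELS <- c("HEOG", "VEOG")
MASTOIDS <- c("M1", "M2")
ALL_CHANNELS <- c(EEG_CHANNELS, EOG_CHANNELS, MASTOIDS)

# Left/right hemisphere electrode of each pair (left listed first).
ELECTRODE_PAIRS <- list("PO7/PO8" = c("PO7", "PO8"),
                        "O1/O2" = c("O1", "O2"),
                        "PO3/PO4" = c("PO3", "PO4"))

# Hemifield of each letter location: 1,2 left of fixation; 3,4 right.
hemifield <- function(location) ifelse(location <= 2, "left", "right")

# Contralateral electrode of a pair for a stimulus location.
contra_channel <- function(pair, location) {
  if (hemifield(location) == "left") pair[2] else pair[1]
}

#' Band-limited pink (1/f) background noise
#'
#' Generates Gaussian 1/f-amplitude noise by spectral shaping, normalized
#' to a target standard deviation. Used as the background EEG process;
#' its spectrum falls off like real resting EEG and therefore exercises
#' the band-pass filters more realistically than white noise.
#'
#' @param n Number of samples.
#' @param sd Target standard deviation (microvolts).
#' @return Numeric vector of length `n`. Draws from the current RNG state.
#' @export
pink_noise <- function(n, sd = 1) {
  if (sd == 0 || n == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(1, seq_len(m - 1)) # avoid DC blow-up; bin index as frequency proxy
  f <- pmin(f, m - f + 1) # two-sided symmetric shaping
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  sd * (y - mean(y)) / stats::sd(y)
}

# Half-cosine-windowed boxcar of n samples with ramp_n-sample raised-cosine
# edges (Tukey-style); peak value 1.
component_shape <- function(n, ramp_n) {
  if (n <= 0) return(numeric(0))
  w <- rep(1, n)
  r <- min(ramp_n, floor(n / 2))
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / (r + 1)))
    w[seq_len(r)] <- ramp
    w[n + 1 - seq_len(r)] <- rev(ramp)
  }
  w
}

new_recording <- function(data, fs, events) {
  stopifnot(ncol(data) == length(ALL_CHANNELS))
  colnames(data) <- ALL_CHANNELS
  structure(list(data = data, channels = ALL_CHANNELS, fs = fs,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "samples x", ncol(x$data),
      "channels @", x$fs, "Hz (", round(nrow(x$data) / x$fs, 1), "s )\n")
  cat("  events:", nrow(x$events), "(",
      paste(names(table(x$events$kind)), table(x$events$kind),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Synthesize one subject's continuous EEG recording
#'
#' Renders a trial schedule into a continuous multi-channel recording in
#' microvolts. For every trial, cue-locked components (an early N2pc-like
#' and a late SPCN-like contralateral wave) are added to the electrode of
#' each posterior pair contralateral to the cued hemifield, and
#' target-locked components (early P1-like and late contralateral
#' positivities) are added at each letter flash, at full amplitude when
#' the letter is at the cued location and scaled by
#' `truth$unattended_scale` otherwise. Pink background noise is added per
#' channel; mastoids carry near-zero reference noise so re-referencing is
#' exercised.
#'
#' @param schedule A [generate_schedule()] result.
#' @param truth A [ground_truth()].
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An `eeg_recording`: microvolt sample matrix (rows = samples,
#'   columns = channels PO7, PO8, O1, O2, PO3, PO4, HEOG, VEOG, M1, M2),
#'   sampling rate, and an event table with columns `sample`, `kind`
#'   (`"cue"` or `"flash"`), `location` (cued location for cue events,
#'   letter location for flashes) and `cued` (the trial's cued location).
#' @export
synthesize_subject <- function(schedule, truth = ground_truth(), seed = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"), inherits(truth, "ground_truth"))
  design <- attr(schedule, "design")
  fs <- design$sampling_rate_hz
  K <- design$n_locations
  flash_cols <- as.matrix(schedule[, grep("^f[0-9]+_[12]$", names(schedule))])
  n_samp <- ceiling((max(flash_cols) + 1.2) * fs)

  set.seed(as.integer(seed))
  data <- matrix(0, n_samp, length(ALL_CHANNELS))
  colnames(data) <- ALL_CHANNELS
  if (truth$noise_sd_uv > 0)
    for (ch in EEG_CHANNELS)
      data[, ch] <- pink_noise(n_samp, truth$noise_sd_uv)
  if (truth$eog_noise_sd_uv > 0)
    for (ch in EOG_CHANNELS)
      data[, ch] <- pink_noise(n_samp, truth$eog_noise_sd_uv)
  if (truth$noise_sd_uv > 0)
    for (ch in MASTOIDS)
      data[, ch] <- pink_noise(n_samp, truth$noise_sd_uv * 0.02)

  lat <- truth$component_latencies_ms
  ramp_n <- round(truth$edge_ramp_ms / 1000 * fs)
  comp_idx <- function(onset_s, window_ms) {
    a <- round((onset_s + window_ms[1] / 1000) * fs) + 1L
    len <- round(diff(window_ms) / 1000 * fs)
    if (a + len - 1L > n_samp)
      stop("component extends beyond the end of the recording")
    seq.int(a, length.out = len)
  }
  shapes <- lapply(lat, function(w)
    component_shape(round(diff(w) / 1000 * fs), ramp_n))

  add_component <- function(onset_s, window_ms, shape, location, amp) {
    if (amp == 0) return(invisible())
    idx <- comp_idx(onset_s, window_ms)
    for (p in names(ELECTRODE_PAIRS)) {
      ch <- contra_channel(ELECTRODE_PAIRS[[p]], location)
      data[idx, ch] <<- data[idx, ch] + amp * truth$pair_gains[[p]] * shape
    }
  }

  ev <- vector("list", nrow(schedule))
  for (t in seq_len(nrow(schedule))) {
    L <- schedule$location[t]
    cue_on <- schedule$cue_onset[t]
    add_component(cue_on, lat$cue_early, shapes$cue_early, L,
                  truth$cue_early_amp[L])
    add_component(cue_on, lat$cue_late, shapes$cue_late, L,
                  truth$cue_late_amp[L])
    if (truth$heog_drift_uv != 0) {
      idx <- comp_idx(cue_on, c(200, 1000))
      sgn <- if (hemifield(L) == "left") -1 else 1
      data[idx, "HEOG"] <- data[idx, "HEOG"] +
        sgn * truth$heog_drift_uv * component_shape(length(idx), ramp_n * 4)
    }
    rows <- list(data.frame(sample = round(cue_on * fs) + 1L, kind = "cue",
                            location = L, cued = L))
    for (m in seq_len(K)) {
      scale <- if (m == L) 1 else truth$unattended_scale
      for (k in 1:2) {
        f_on <- schedule[[paste0("f", m, "_", k)]][t]
        add_component(f_on, lat$target_early, shapes$target_early, m,
                      truth$target_early_amp[m] * scale)
        add_component(f_on, lat$target_late, shapes$target_late, m,
                      truth$target_late_amp[m] * scale)
        rows[[length(rows) + 1L]] <-
          data.frame(sample = round(f_on * fs) + 1L, kind = "flash",
                     location = m, cued = L)
      }
    }
    ev[[t]] <- do.call(rbind, rows)
  }
  events <- do.call(rbind, ev)
  stopifnot(all(events$sample >= 1), all(events$sample <= n_samp))
  new_recording(data, fs, events)
}

#' Add a single blink or saccade template to a recording
#'
#' `add_blink()` adds a raised-cosine VEOG deflection (default 200 ms long,
#' so the rise occurs within 100 ms) with partial leakage into the EEG
#' channels. `add_saccade()` adds a step-like HEOG deflection (30 ms rise,
#' 400 ms hold, 100 ms return) with small EEG leakage.
#'
#' @param recording An `eeg_recording`.
#' @param sample Onset sample of the template.
#' @param amp_uv Peak amplitude in microvolts.
#' @param duration_ms Blink duration (rise + fall).
#' @param leakage Fraction of the template added to each EEG channel.
#' @param direction +1 or -1, saccade direction.
#' @return The modified `eeg_recording`.
#' @export
add_blink <- function(recording, sample, amp_uv = 150, duration_ms = 200,
                      leakage = 0.1) {
  fs <- recording$fs
  n <- round(duration_ms / 1000 * fs)
  tpl <- amp_uv * 0.5 * (1 - cos(2 * pi * seq_len(n) / n))
  idx <- seq.int(sample, length.out = n)
  idx_ok <- idx <= nrow(recording$data) & idx >= 1
  recording$data[idx[idx_ok], "VEOG"] <-
    recording$data[idx[idx_ok], "VEOG"] + tpl[idx_ok]
  for (ch in EEG_CHANNELS)
    recording$data[idx[idx_ok], ch] <-
      recording$data[idx[idx_ok], ch] + leakage * tpl[idx_ok]
  recording
}

#' @rdname add_blink
#' @export
add_saccade <- function(recording, sample, amp_uv = 60, direction = 1,
                        leakage = 0.1) {
  fs <- recording$fs
  rise <- round(0.030 * fs); hold <- round(0.400 * fs); fall <- round(0.100 * fs)
  tpl <- direction * amp_uv *
    c(seq(0, 1, length.out = rise), rep(1, hold), seq(1, 0, length.out = fall))
  idx <- seq.int(sample, length.out = length(tpl))
  idx_ok <- idx <= nrow(recording$data) & idx >= 1
  recording$data[idx[idx_ok], "HEOG"] <-
    recording$data[idx[idx_ok], "HEOG"] + tpl[idx_ok]
  for (ch in EEG_CHANNELS)
    recording$data[idx[idx_ok], ch] <-
      recording$data[idx[idx_ok], ch] + leakage * tpl[idx_ok]
  recording
}

#' Inject ocular artifacts at random times
#'
#' Adds blink and saccade templates at uniformly random times. Event
#' counts are Poisson with mean `rate * n_trials` per artifact kind.
#' Every injected event is returned with its onset sample and kind, so
#' downstream rejection can be scored against ground truth.
#'
#' @param recording An `eeg_recording`.
#' @param rates Named vector `c(blink=, saccade=)`, expected events per trial.
#' @param seed Integer seed.
#' @param blink_amp_uv,saccade_amp_uv Template peak amplitudes, microvolts.
#' @return List with elements `recording` (modified) and `log` (data frame
#'   of `sample`, `kind`, `amp_uv`). With all rates zero the recording is
#'   returned unchanged and the log is empty.
#' @export
inject_artifacts <- function(recording, rates = c(blink = 0.05, saccade = 0.05),
                             seed = 1L, blink_amp_uv = 150,
                             saccade_amp_uv = 60) {
  stopifnot(all(rates >= 0))
  log <- data.frame(sample = integer(0), kind = character(0),
                    amp_uv = numeric(0))
  if (all(rates == 0)) return(list(recording = recording, log = log))
  set.seed(as.integer(seed))
  n_trials <- sum(recording$events$kind == "cue")
  n_samp <- nrow(recording$data)
  lo <- round(0.5 * recording$fs); hi <- n_samp - recording$fs
  draw <- function(kind, rate) {
    n <- stats::rpois(1, rate * n_trials)
    if (n == 0) return(NULL)
    data.frame(sample = sort(sample(seq.int(lo, hi), n)), kind = kind,
               amp_uv = if (kind == "blink") blink_amp_uv else saccade_amp_uv)
  }
  log <- rbind(draw("blink", rates[["blink"]]),
               draw("saccade", rates[["saccade"]]))
  if (is.null(log) || nrow(log) == 0)
    return(list(recording = recording,
                log = data.frame(sample = integer(0), kind = character(0),
                                 amp_uv = numeric(0))))
  for (i in seq_len(nrow(log))) {
    recording <- if (log$kind[i] == "blink")
      add_blink(recording, log$sample[i], blink_amp_uv)
    else
      add_saccade(recording, log$sample[i], saccade_amp_uv,
                  direction = sample(c(-1, 1), 1))
  }
  list(recording = recording, log = log)
}

#' Simulate feature tables directly (no EEG rendering)
#'
#' Draws per-(subject, location) 12-dimensional lateralized-amplitude
#' feature rows from the same geometry the EEG generator induces: each
#' feature is a fixed gain times a signed location coordinate
#' (`+ecc, +1, -1, -ecc` for locations 1..4, hemifield-signed and
#' eccentricity-graded) plus Gaussian noise and an optional subject random
#' intercept. Cheap stand-in for the full pipeline when testing the
#' classifier and evaluation machinery.
#'
#' @param n_subjects Number of subjects.
#' @param effect_uv Lateralized effect scale (microvolts); 0 gives pure
#'   noise (chance-level decodable).
#' @param ecc_factor Outer-location amplitude grading (see [ground_truth()]).
#' @param noise_sd_uv Feature noise standard deviation.
#' @param subject_sd_uv Subject random-intercept standard deviation.
#' @param seed Integer seed.
#' @return A feature table (`data.frame`) with columns `subject`,
#'   `location`, and the 12 features of [feature_names()].
#' @export
simulate_features <- function(n_subjects = 15, effect_uv = 1,
                              ecc_factor = 1.5, noise_sd_uv = 0.3,
                              subject_sd_uv = 0, seed = 1L) {
  set.seed(as.integer(seed))
  fn <- feature_names()
  gains <- feature_gains()
  mu_loc <- effect_uv * c(ecc_factor, 1, -1, -ecc_factor)
  rows <- expand.grid(location = 1:4, subject = seq_len(n_subjects))
  rows <- rows[, c("subject", "location")]
  X <- outer(mu_loc[rows$location], gains) +
    matrix(stats::rnorm(nrow(rows) * 12, sd = noise_sd_uv), nrow(rows), 12)
  if (subject_sd_uv > 0)
    X <- X + stats::rnorm(n_subjects, sd = subject_sd_uv)[rows$subject]
  colnames(X) <- fn
  cbind(rows, as.data.frame(X))
}

#' Simulate target-locked attended/unattended feature tables
#'
#' One row per (subject, cued location, letter location): the six
#' target-locked lateralized features for letters at the cued location
#' carry the full hemifield-signed effect, letters at uncued locations a
#' fraction `unattended_scale` of it. The attended label is true when the
#' cue and letter locations coincide (1 in 4 rows by design).
#'
#' @inheritParams simulate_features
#' @param unattended_scale Amplitude multiplier for uncued letters.
#' @return `data.frame` with columns `subject`, `cue_location`,
#'   `letter_location`, `attended` (logical) and the 6 target features.
#' @export
simulate_attended_features <- function(n_subjects = 15, effect_uv = 1,
                                       ecc_factor = 1.5,
                                       unattended_scale = 0.2,
                                       noise_sd_uv = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  fn <- feature_names(locks = "target")
  gains <- feature_gains()[feature_names() %in% fn]
  rows <- expand.grid(letter_location = 1:4, cue_location = 1:4,
                      subject = seq_len(n_subjects))
  rows <- rows[, c("subject", "cue_location", "letter_location")]
  rows$attended <- rows$cue_location == rows$letter_location
  grade <- c(ecc_factor, 1, 1, ecc_factor)
  sgn <- ifelse(rows$letter_location <= 2, 1, -1)
  amp <- effect_uv * grade[rows$letter_location] * sgn *
    ifelse(rows$attended, 1, unattended_scale)
  X <- outer(amp, gains) +
    matrix(stats::rnorm(nrow(rows) * length(fn), sd = noise_sd_uv),
           nrow(rows), length(fn))
  colnames(X) <- fn
  cbind(rows, as.data.frame(X))
}
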