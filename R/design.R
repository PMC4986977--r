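#' Task design for the modified Posner cueing experiment
#'
#' Describes the timing and geometry of the cueing task: four letter
#' locations arrayed left to right on the horizontal midline (two per
#' hemifield), a 250 ms endogenous grid cue at one location, a random
#' 450--550 ms cue--letter delay, and four letters each flashed twice for
#' 33 ms (minimum 17 ms between the flashes of a letter) inside a 200 ms
#' presentation window.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block. `n_blocks * trials_per_block`
#'   must be divisible by `n_locations` so the schedule can be balanced.
#' @param n_locations Number of cue/letter locations (fixed at 4).
#' @param cue_duration_ms Cue duration in ms.
#' @param delay_range_ms Length-2 numeric, uniform range of the delay
#'   between cue offset and the letter presentation window, in ms.
#' @param flash_duration_ms Duration of a single letter flash, in ms.
#' @param min_interflash_gap_ms Minimum gap between the two flashes of the
#'   same letter, in ms.
#' @param presentation_window_ms Length of the letter presentation window,
#'   in ms.
#' @param horizontal_gap_deg Horizontal centre-to-centre gap between
#'   adjacent letter locations, in degrees of visual angle.
#' @param vertical_gap_deg Vertical gap between the two stimulus rows, in
#'   degrees of visual angle.
#' @param sampling_rate_hz EEG sampling rate in Hz.
#'
#' @return An object of class `task_design` (a named list).
#' @examples
#' d <- task_design()
#' d$n_blocks * d$trials_per_block # 600 trials
#' @export
task_design <- function(n_blocks = 2L,
                        trials_per_block = 300L,
                        n_locations = 4L,
                        cue_duration_ms = 250,
                        delay_range_ms = c(450, 550),
                        flash_duration_ms = 33,
                        min_interflash_gap_ms = 17,
                        presentation_window_ms = 200,
                        horizontal_gap_deg = 0.88,
                        vertical_gap_deg = 2.05,
                        sampling_rate_hz = 512) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1, n_locations >= 2,
            length(delay_range_ms) == 2, delay_range_ms[1] <= delay_range_ms[2],
            sampling_rate_hz > 0)
  if (2 * flash_duration_ms + min_interflash_gap_ms > presentation_window_ms)
    stop("infeasible flash timing: 2*flash_duration + min_gap exceeds the presentation window")
  structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_locations = as.integer(n_locations),
    cue_duration_ms = cue_duration_ms,
    delay_range_ms = delay_range_ms,
    flash_duration_ms = flash_duration_ms,
    min_interflash_gap_ms = min_interflash_gap_ms,
    presentation_window_ms = presentation_window_ms,
    horizontal_gap_deg = horizontal_gap_deg,
    vertical_gap_deg = vertical_gap_deg,
    sampling_rate_hz = sampling_rate_hz
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Posner-task design:", x$n_blocks, "block(s) x", x$trials_per_block,
      "trials,", x$n_locations, "locations\n")
  cat("  cue", x$cue_duration_ms, "ms; delay",
      paste(x$delay_range_ms, collapse = "-"), "ms; 2 x",
      x$flash_duration_ms, "ms flashes (gap >=", x$min_interflash_gap_ms,
      "ms) in a", x$presentation_window_ms, "ms window\n")
  cat("  sampling rate", x$sampling_rate_hz, "Hz\n")
  invisible(x)
}

#' Ground-truth generative parameters for synthetic lateralized ERPs
#'
#' Defines the amplitudes, latencies and noise of the simulated lateralized
#' components. Amplitudes are *contralateral* amplitudes in microvolts: a
#' component of amplitude `a` for a location in the left hemifield
#' (locations 1, 2) is added to the right-hemisphere electrode of each
#' pair, and vice versa, so a contralateral *negativity* (`a < 0`) yields a
#' positive left-minus-right difference wave for left-hemifield locations
#' and a negative one for right-hemifield locations (mirrored).
#'
#' Four components are simulated, all half-cosine-windowed boxcars:
#' an early cue-locked negativity (N2pc-like), a late sustained cue-locked
#' negativity (SPCN-like), an early target-locked positivity (P1-like) and
#' a late target-locked positivity. Target-locked components are emitted at
#' full amplitude for letters flashed at the cued location and scaled by
#' `unattended_scale` for letters at uncued locations.
#'
#' @param cue_early_amp_uv,cue_late_amp_uv,target_early_amp_uv,target_late_amp_uv
#'   Base contralateral amplitude of each component in microvolts (negative
#'   = contralateral negativity). Scalars; per-location amplitudes are
#'   obtained by multiplying with the eccentricity grading.
#' @param ecc_factor Eccentricity grading: outer locations (1 and 4)
#'   receive `ecc_factor` times the base amplitude, inner locations (2, 3)
#'   the base amplitude.
#' @param component_latencies_ms Named list of `c(onset, offset)` windows
#'   (ms, relative to the locking event) for components `cue_early`,
#'   `cue_late`, `target_early`, `target_late`.
#' @param edge_ramp_ms Half-cosine ramp length at each component edge, ms.
#' @param pair_gains Per-electrode-pair gain applied to component
#'   amplitudes, named for pairs PO7/PO8, O1/O2, PO3/PO4.
#' @param unattended_scale Multiplier on target-locked amplitudes for
#'   letters flashed at uncued locations.
#' @param noise_sd_uv Standard deviation of the background pink noise per
#'   EEG channel, microvolts.
#' @param eog_noise_sd_uv Standard deviation of EOG channel noise,
#'   microvolts.
#' @param heog_drift_uv Amplitude of a slow residual-gaze HEOG deflection
#'   toward the cued hemifield (used by the ocular-confound analysis);
#'   0 disables it.
#' @param blink_rate,saccade_rate Expected injected artifact events per
#'   trial (see [inject_artifacts()]); the generator itself adds none.
#'
#' @return An object of class `ground_truth` (a named list) with the
#'   per-location amplitude vectors in elements `cue_early_amp`,
#'   `cue_late_amp`, `target_early_amp`, `target_late_amp`.
#' @export
ground_truth <- function(cue_early_amp_uv = -1.0,
                         cue_late_amp_uv = -2.0,
                         target_early_amp_uv = 1.5,
                         target_late_amp_uv = 2.0,
                         ecc_factor = 1.5,
                         component_latencies_ms = list(
                           cue_early = c(170, 270),
                           cue_late = c(400, 840),
                           target_early = c(0, 130),
                           target_late = c(400, 540)
                         ),
                         edge_ramp_ms = 20,
                         pair_gains = c("PO7/PO8" = 1.0, "O1/O2" = 0.9,
                                        "PO3/PO4" = 0.8),
                         unattended_scale = 0.2,
                         noise_sd_uv = 10,
                         eog_noise_sd_uv = 5,
                         heog_drift_uv = 0,
                         blink_rate = 0,
                         saccade_rate = 0) {
  stopifnot(noise_sd_uv >= 0, eog_noise_sd_uv >= 0, ecc_factor > 0,
            blink_rate >= 0, saccade_rate >= 0)
  amps <- vapply(list(cue_early_amp_uv, cue_late_amp_uv,
                      target_early_amp_uv, target_late_amp_uv),
                 function(a) { stopifnot(is.finite(a)); a }, numeric(1))
  grade <- c(ecc_factor, 1, 1, ecc_factor) # locations 1..4
  structure(list(
    cue_early_amp = amps[1] * grade,
    cue_late_amp = amps[2] * grade,
    target_early_amp = amps[3] * grade,
    target_late_amp = amps[4] * grade,
    ecc_factor = ecc_factor,
    component_latencies_ms = component_latencies_ms,
    edge_ramp_ms = edge_ramp_ms,
    pair_gains = pair_gains,
    unattended_scale = unattended_scale,
    noise_sd_uv = noise_sd_uv,
    eog_noise_sd_uv = eog_noise_sd_uv,
    heog_drift_uv = heog_drift_uv,
    artifact_rates = c(blink = blink_rate, saccade = saccade_rate)
  ), class = "ground_truth")
}

#' Generate a balanced, randomly ordered trial schedule
#'
#' Draws a trial schedule for one subject: cued locations balanced exactly
#' across trials (each location cued `n_trials / n_locations` times) in
#' random order, with per-trial event times. Each trial contains a cue
#' onset, a uniformly drawn cue--letter delay, and for every letter
#' location two flash onsets inside the presentation window respecting the
#' flash duration and minimum inter-flash gap.
#'
#' @param design A [task_design()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param start_s Time of the first cue onset, seconds.
#' @param iti_s Interval between the end of one trial's presentation window
#'   (plus the post-stimulus epoch span) and the next cue onset, seconds.
#'
#' @return A `trial_schedule`: a data frame with one row per trial and
#'   columns `trial`, `block`, `location`, `cue_onset` (s), `win_start`
#'   (presentation-window onset, s), and flash onsets `f<loc>_1`,
#'   `f<loc>_2` (s) for each letter location, with the
#'   design attached as attribute `design`.
#' @examples
#' sch <- generate_schedule(task_design(n_blocks = 1, trials_per_block = 8), seed = 1)
#' table(sch$location)
#' @export
generate_schedule <- function(design = task_design(), seed = 1L,
                              start_s = 1.0, iti_s = 0.3) {
  stopifnot(inherits(design, "task_design"))
  n_trials <- design$n_blocks * design$trials_per_block
  K <- design$n_locations
  if (n_trials %% K != 0L)
    stop("unbalanced design: total trial count (", n_trials,
         ") is not divisible by the number of locations (", K, ")")
  set.seed(as.integer(seed))
  location <- sample(rep(seq_len(K), n_trials / K))

  cue_dur <- design$cue_duration_ms / 1000
  win <- design$presentation_window_ms / 1000
  fl <- design$flash_duration_ms / 1000
  gap <- design$min_interflash_gap_ms / 1000
  delay <- stats::runif(n_trials, design$delay_range_ms[1],
                        design$delay_range_ms[2]) / 1000

  # latest admissible first-flash onset leaves room for flash + gap + flash
  f1_max <- win - 2 * fl - gap
  trial_len <- cue_dur + max(design$delay_range_ms) / 1000 + win + 0.9 + iti_s
  cue_onset <- start_s + (seq_len(n_trials) - 1L) * trial_len
  win_start <- cue_onset + cue_dur + delay

  flashes <- matrix(NA_real_, n_trials, 2L * K)
  for (k in seq_len(K)) {
    f1 <- stats::runif(n_trials, 0, f1_max)
    f2 <- stats::runif(n_trials, f1 + fl + gap, win - fl)
    flashes[, 2L * k - 1L] <- win_start + f1
    flashes[, 2L * k] <- win_start + f2
  }
  colnames(flashes) <- paste0("f", rep(seq_len(K), each = 2), "_", 1:2)

  out <- data.frame(
    trial = seq_len(n_trials),
    block = rep(seq_len(design$n_blocks), each = design$trials_per_block),
    location = location,
    cue_onset = cue_onset,
    win_start = win_start,
    flashes
  )
  attr(out, "design") <- design
  class(out) <- c("trial_schedule", "data.frame")
  out
}
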