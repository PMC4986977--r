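#' Feature extraction specification
#'
#' Electrode pairs and analysis windows for the 12 lateralized ERP
#' features: {cue, target} lock x {PO7/PO8, O1/O2, PO3/PO4} pair x
#' {early, late} window. Cue-locked windows default to 170--270 ms
#' (N2pc range) and 650--840 ms (within the SPCN); target-locked windows
#' to 0--100 ms (early contralateral P1, early because the average pools
#' both letter flashes) and 410--530 ms (late contralateral positivity).
#' Window endpoints are half-open `[onset, offset)`.
#'
#' @param pairs Named list of electrode pairs, left channel first.
#' @param cue_windows_ms,target_windows_ms Named lists (`early`, `late`)
#'   of length-2 windows in ms.
#' @param jitter_ms Window jitter used by robustness checks, ms.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(pairs = ELECTRODE_PAIRS,
                         cue_windows_ms = list(early = c(170, 270),
                                               late = c(650, 840)),
                         target_windows_ms = list(early = c(0, 100),
                                                  late = c(410, 530)),
                         jitter_ms = 20) {
  for (p in pairs) stopifnot(length(p) == 2)
  structure(list(pairs = pairs, cue_windows_ms = cue_windows_ms,
                 target_windows_ms = target_windows_ms,
                 jitter_ms = jitter_ms),
            class = "feature_spec")
}

#' Canonical feature names
#'
#' Stable column names of the feature table, in the order
#' lock (cue, target) x electrode pair x window (early, late), e.g.
#' `cue_PO7_PO8_early`.
#'
#' @param locks,pairs,windows Subsets to restrict to.
#' @return Character vector (length 12 for the defaults).
#' @examples
#' feature_names()
#' feature_names(locks = "cue") # the 6 cue-locked features
#' @export
feature_names <- function(locks = c("cue", "target"),
                          pairs = names(ELECTRODE_PAIRS),
                          windows = c("early", "late")) {
  unlist(lapply(locks, function(l)
    lapply(pairs, function(p)
      paste(l, gsub("/", "_", p), windows, sep = "_"))))
}

# Fixed per-feature gains used by the feature-level simulators: the
# relative strength with which each feature expresses the lateralized
# location coordinate (lock x pair x window attenuation).
feature_gains <- function() {
  lock_w <- c(cue = 1, target = 0.85)
  pair_w <- c(1, 0.9, 0.8)
  win_w <- c(early = 0.9, late = 1)
  g <- as.numeric(outer(win_w, outer(pair_w, lock_w))) # window fastest
  names(g) <- feature_names()
  g
}

#' Average kept epochs for one condition
#'
#' Point-wise mean over the *kept* epochs of one cued location. For
#' cue-locked epoch sets all epochs of trials cued at `cued_location`
#' enter the average; for flash-locked sets the epochs of the letter at
#' `letter_location` (default: the cued letter, pooling both of its
#' flashes) within those trials.
#'
#' @param epochs An `epoch_set`.
#' @param cued_location Cued location (1--4) of the trials to include.
#' @param letter_location For flash-locked sets, the letter whose flashes
#'   define t = 0; defaults to `cued_location`.
#' @return An `erp_average`: list with `data` (channels x samples matrix),
#'   `channels`, `times`, and `n` (number of epochs averaged).
#' @export
average_epochs <- function(epochs, cued_location, letter_location = NULL) {
  sel <- epochs$info$kept & epochs$info$cued == cued_location
  if (epochs$lock == "flash") {
    if (is.null(letter_location)) letter_location <- cued_location
    sel <- sel & epochs$info$location == letter_location
  }
  if (!any(sel))
    stop("no kept epochs for cued location ", cued_location,
         if (epochs$lock == "flash") paste0(", letter ", letter_location))
  d <- epochs$data[sel, , , drop = FALSE]
  avg <- apply(d, c(2, 3), mean)
  structure(list(data = avg, channels = epochs$channels,
                 times = epochs$times, n = sum(sel)),
            class = "erp_average")
}

#' Lateralized (left-minus-right) difference wave
#'
#' Subtracts the right-hemisphere electrode's waveform from the
#' left-hemisphere electrode's, sample-wise (e.g. PO7 minus PO8), so a
#' contralateral negativity appears as a positive difference for
#' left-hemifield stimuli and a negative one for right-hemifield stimuli.
#'
#' @param avg An `erp_average`.
#' @param pair Pair name (`"PO7/PO8"`) or a character pair, left first.
#' @return Numeric waveform with a `times` attribute (seconds).
#' @export
lateralized_wave <- function(avg, pair) {
  if (is.character(pair) && length(pair) == 1) {
    if (!pair %in% names(ELECTRODE_PAIRS)) stop("unknown electrode pair: ", pair)
    pair <- ELECTRODE_PAIRS[[pair]]
  }
  if (!all(pair %in% avg$channels)) stop("unknown electrode pair: ",
                                         paste(pair, collapse = "/"))
  w <- avg$data[pair[1], ] - avg$data[pair[2], ]
  attr(w, "times") <- avg$times
  w
}

#' Mean amplitude over a time window
#'
#' Mean of the waveform samples with `onset <= t < offset` (half-open,
#' matching the epoch convention).
#'
#' @param wave Numeric waveform with a `times` attribute, or plain vector
#'   with `times` supplied.
#' @param window_ms Length-2 window in ms.
#' @param times Sample times in seconds (defaults to `attr(wave, "times")`).
#' @return Mean amplitude (microvolts).
#' @export
window_mean <- function(wave, window_ms, times = attr(wave, "times")) {
  stopifnot(!is.null(times), length(times) == length(wave))
  sel <- times >= window_ms[1] / 1000 & times < window_ms[2] / 1000
  if (!any(sel)) stop("window [", window_ms[1], ", ", window_ms[2],
                      ") ms contains no samples")
  mean(wave[sel])
}

#' Extract the 12 lateralized ERP features per subject and location
#'
#' For every subject and cued location, averages the kept cue-locked and
#' target-locked (cued letter, both flashes pooled) epochs, forms the
#' three left-minus-right difference waves, and takes mean amplitudes
#' over the early and late windows: 2 locks x 3 pairs x 2 windows = 12
#' features. Subjects missing kept epochs for any location are dropped
#' with a warning.
#'
#' @param subjects A single [preprocess_subject()] result or a (optionally
#'   named) list of them.
#' @param spec A [feature_spec()].
#' @param jitter_ms Optional scalar added to every window edge (used by
#'   robustness checks).
#' @return Feature table: `data.frame` with `subject`, `location` and the
#'   12 columns of [feature_names()].
#' @export
extract_features <- function(subjects, spec = feature_spec(), jitter_ms = 0) {
  if (!is.null(names(subjects)) && all(c("cue", "target") %in% names(subjects)))
    subjects <- list(`1` = subjects)
  if (is.null(names(subjects))) names(subjects) <- seq_along(subjects)
  locs <- sort(unique(subjects[[1]]$cue$info$cued))
  rows <- list()
  for (s in names(subjects)) {
    sub <- subjects[[s]]
    tab <- tryCatch({
      do.call(rbind, lapply(locs, function(L) {
        cue_avg <- average_epochs(sub$cue, L)
        tgt_avg <- average_epochs(sub$target, L)
        amps <- function(avg, wins)
          unlist(lapply(names(spec$pairs), function(p) {
            w <- lateralized_wave(avg, p)
            vapply(wins, function(win) window_mean(w, win + jitter_ms),
                   numeric(1))
          }))
        vals <- c(amps(cue_avg, spec$cue_windows_ms),
                  amps(tgt_avg, spec$target_windows_ms))
        names(vals) <- feature_names()
        cbind(data.frame(subject = s, location = L), as.data.frame(t(vals)))
      }))
    }, error = function(e) {
      warning("subject ", s, " dropped: ", conditionMessage(e))
      NULL
    })
    rows[[s]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract target-locked attended/unattended features
#'
#' One row per (subject, cued location, letter location) with the six
#' target-locked lateralized features computed from the kept flash
#' epochs of that letter within trials of that cue. A row is attended
#' when the cue and letter locations coincide.
#'
#' @inheritParams extract_features
#' @return `data.frame` with `subject`, `cue_location`, `letter_location`,
#'   `attended` and the 6 target-locked feature columns.
#' @export
extract_attended_features <- function(subjects, spec = feature_spec()) {
  if (!is.null(names(subjects)) && all(c("cue", "target") %in% names(subjects)))
    subjects <- list(`1` = subjects)
  if (is.null(names(subjects))) names(subjects) <- seq_along(subjects)
  fn <- feature_names(locks = "target")
  rows <- list()
  for (s in names(subjects)) {
    tgt <- subjects[[s]]$target
    locs <- sort(unique(tgt$info$cued))
    for (cl in locs) for (ll in locs) {
      avg <- tryCatch(average_epochs(tgt, cl, ll), error = function(e) NULL)
      if (is.null(avg)) next
      vals <- unlist(lapply(names(spec$pairs), function(p) {
        w <- lateralized_wave(avg, p)
        vapply(spec$target_windows_ms, function(win) window_mean(w, win),
               numeric(1))
      }))
      names(vals) <- fn
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject = s, cue_location = cl, letter_location = ll,
                         attended = cl == ll), as.data.frame(t(vals)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject lateralized HEOG amplitude
#'
#' Summary of residual eye movement toward the cued hemifield: the
#' absolute cue-locked average HEOG amplitude at `at_ms` after cue onset,
#' averaged over cued locations. Used to split subjects for the
#' ocular-confound analysis.
#'
#' @param cue_epochs A cue-locked `epoch_set` for one subject.
#' @param at_ms Latency of the measurement, ms after cue onset.
#' @return Non-negative scalar (microvolts).
#' @export
heog_amplitude <- function(cue_epochs, at_ms = 500) {
  locs <- sort(unique(cue_epochs$info$cued))
  idx <- which.min(abs(cue_epochs$times - at_ms / 1000))
  mean(vapply(locs, function(L) {
    avg <- average_epochs(cue_epochs, L)
    abs(avg$data["HEOG", idx])
  }, numeric(1)))
}
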