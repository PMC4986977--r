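#' Simulate and preprocess a whole multi-subject study
#'
#' Runs the full front half of the pipeline for `n_subjects` synthetic
#' subjects: trial schedule, continuous EEG synthesis, optional artifact
#' injection, preprocessing (re-reference, filter, epoch, baseline,
#' artifact rejection), subject exclusion by rejection rate, and feature
#' extraction. All randomness derives from `seed` by a fixed splitting
#' scheme: subject i uses seeds `seed + 7919*i + {0,1,2}` for its
#' schedule, EEG noise and artifact draws.
#'
#' @param n_subjects Number of subjects.
#' @param design A [task_design()].
#' @param truth A [ground_truth()]; its `artifact_rates` drive injection.
#' @param criteria A [rejection_criteria()].
#' @param spec A [feature_spec()].
#' @param seed Integer master seed.
#' @param heog_drift_uv Per-subject residual-gaze HEOG amplitudes
#'   (recycled to `n_subjects`); creates between-subject eye-movement
#'   differences for the ocular-confound analysis.
#' @param attended Also extract the attended/unattended feature table?
#' @return List with `features` (subjects x locations x 12), `attended`
#'   (or `NULL`), `heog` (named per-subject HEOG summaries),
#'   `rejection_rates`, and `subjects` (ids retained after exclusion).
#' @export
simulate_study <- function(n_subjects = 15, design = task_design(),
                           truth = ground_truth(),
                           criteria = rejection_criteria(),
                           spec = feature_spec(), seed = 1L,
                           heog_drift_uv = 0, attended = FALSE) {
  heog_drift_uv <- rep_len(heog_drift_uv, n_subjects)
  feats <- list(); atts <- list()
  heog <- numeric(0); rates <- numeric(0)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    s <- as.integer(seed) + 7919L * i
    tr <- truth
    tr$heog_drift_uv <- heog_drift_uv[i]
    sch <- generate_schedule(design, seed = s)
    rec <- synthesize_subject(sch, tr, seed = s + 1L)
    if (any(tr$artifact_rates > 0))
      rec <- inject_artifacts(rec, tr$artifact_rates, seed = s + 2L)$recording
    prep <- preprocess_subject(rec, criteria)
    rates[sid] <- prep$rejection_rate
    heog[sid] <- heog_amplitude(prep$cue)
    ft <- extract_features(prep, spec)
    ft$subject <- sid
    feats[[sid]] <- ft
    if (attended) {
      at <- extract_attended_features(prep, spec)
      at$subject <- sid
      atts[[sid]] <- at
    }
    rm(rec, prep); gc(FALSE)
  }
  kept <- exclude_subjects(rates, criteria)
  features <- do.call(rbind, feats[kept])
  rownames(features) <- NULL
  att <- if (attended) {
    a <- do.call(rbind, atts[kept]); rownames(a) <- NULL; a
  } else NULL
  list(features = features, attended = att, heog = heog[kept],
       rejection_rates = rates, subjects = kept)
}
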