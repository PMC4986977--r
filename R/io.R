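# Plain-text interchange surfaces between the pipeline halves.

#' Read and write feature tables as tidy CSV
#'
#' The feature CSV (one row per subject x location, 12 named amplitude
#' columns in microvolts) is the interchange surface between the
#' preprocessing/feature half of the pipeline and the decoding half.
#'
#' @param features Feature table (see [extract_features()]).
#' @param path File path.
#' @return `read_features()` returns the feature table.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  ft <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject", "location"), names(ft))
  if (length(missing)) stop("feature CSV lacks columns: ",
                            paste(missing, collapse = ", "))
  ft
}

#' Write an event log as tab-separated values
#'
#' Columns: sample, kind, location (and cued, when present).
#'
#' @param events Event table of an `eeg_recording`.
#' @param path File path.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the per-epoch rejection log as TSV
#'
#' Columns: epoch id, kept flag and rejection reason.
#'
#' @param epochs An `epoch_set` after [reject_artifacts()].
#' @param path File path.
#' @export
write_rejection_log <- function(epochs, path) {
  log <- epochs$info[, c("epoch", "kept", "reason")]
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
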