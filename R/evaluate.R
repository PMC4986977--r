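#' Leave-one-subject-out cross-validated predictions
#'
#' One fold per subject: the dendrogram SVM (tree, node SVMs and feature
#' standardization) is fitted on all remaining subjects' rows and the
#' held-out subject's rows (one per cued location) are predicted.
#' Subjects missing rows for any location are excluded with a warning
#' before folding. Folds are processed in sorted subject order, so
#' predictions do not depend on row order of the input.
#'
#' @param features Feature table: data frame with columns `subject`,
#'   `location` and feature columns.
#' @param feature_cols Feature column names; default all 12 of
#'   [feature_names()] that are present.
#' @param rebuild_tree Rebuild the dendrogram within each training fold
#'   (default, leakage-safe); if `FALSE` one tree is built on the full
#'   table and reused across folds.
#' @param ... Passed to [dsvm()] (`kernel`, `cost`, `gamma`).
#' @return Data frame with one row per (subject, location): `subject`,
#'   `location` (truth) and `predicted`.
#' @export
loso_cv <- function(features, feature_cols = NULL, rebuild_tree = TRUE, ...) {
  if (is.null(feature_cols))
    feature_cols <- intersect(feature_names(), names(features))
  stopifnot(length(feature_cols) >= 1,
            all(c("subject", "location") %in% names(features)))
  locs <- sort(unique(features$location))
  by_subj <- split(features, features$subject)
  complete <- vapply(by_subj, function(d) all(locs %in% d$location),
                     logical(1))
  if (any(!complete)) {
    warning("excluding subject(s) with missing locations: ",
            paste(names(by_subj)[!complete], collapse = ", "))
    features <- features[features$subject %in% names(by_subj)[complete], ]
  }
  subjects <- sort(unique(as.character(features$subject)))
  if (length(subjects) < 3) stop("need at least 3 subjects for LOSO-CV")
  fixed_tree <- if (!rebuild_tree)
    build_dendrogram(features[, feature_cols], features$location) else NULL
  folds <- lapply(subjects, function(s) {
    train <- features[features$subject != s, ]
    test <- features[features$subject == s, ]
    fit <- dsvm(train[, feature_cols, drop = FALSE], train$location,
                tree = fixed_tree, ...)
    data.frame(subject = s, location = test$location,
               predicted = as.integer(as.character(
                 predict(fit, test[, feature_cols, drop = FALSE]))))
  })
  out <- do.call(rbind, folds)
  rownames(out) <- NULL
  attr(out, "n_folds") <- length(subjects)
  out
}

#' Decoding accuracy
#'
#' Percentage of predictions matching the truth. Full precision is
#' returned; use [format_da()] for the truncated display convention
#' (e.g. 10 correct of 15 displays as 66%).
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Accuracy in percent (numeric scalar).
#' @examples
#' decoding_accuracy(c(1, 1, 2), c(1, 2, 2)) # 66.67
#' @export
decoding_accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(predicted) == 0) stop("empty prediction vector")
  100 * mean(as.character(predicted) == as.character(truth))
}

#' Display form of a decoding accuracy
#'
#' Truncates toward zero to a whole percent, the convention under which
#' 10 correct predictions out of 15 display as 66%.
#'
#' @param da_pct Accuracy in percent.
#' @return Integer percent.
#' @examples
#' format_da(100 * 10 / 15) # 66
#' @export
format_da <- function(da_pct) trunc(da_pct)

#' Row-normalized confusion matrix
#'
#' Rows are actual locations, columns predicted; each row holds the
#' proportion of that actual class assigned to each predicted class, so
#' rows sum to 1. Rows for truth classes with no observations are `NaN`
#' and flagged in attribute `undefined_rows`.
#'
#' @param predicted,truth Label vectors.
#' @param levels Class levels (default: sorted union).
#' @return A `confusion_matrix` (numeric matrix with row/col names).
#' @export
confusion_matrix <- function(predicted, truth,
                             levels = sort(unique(c(predicted, truth)))) {
  counts <- table(factor(truth, levels = levels),
                  factor(predicted, levels = levels))
  n <- rowSums(counts)
  cm <- sweep(unclass(as.matrix(counts)), 1, n, "/")
  dimnames(cm) <- list(actual = levels, predicted = levels)
  structure(cm, undefined_rows = levels[n == 0], class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat("Confusion matrix (rows = actual, row-normalized):\n")
  m <- unclass(x)
  attr(m, "undefined_rows") <- NULL
  print(round(m, digits))
  und <- attr(x, "undefined_rows")
  if (length(und)) cat("undefined rows (no support):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Mean letter-position distance between actual and predicted locations
#'
#' D = (1/R) * sum_ij p_ij |i - j|, where p_ij is the row-normalized
#' confusion proportion of predicting location j when i was cued and R
#' the number of rows. Also converts D to degrees of visual angle using
#' the horizontal letter spacing (adjacent locations are one letter
#' position = `gap_deg` apart).
#'
#' @param cm A [confusion_matrix()] with fully normalized rows.
#' @param gap_deg Horizontal gap between adjacent locations, degrees.
#' @return A `distance_result`: list with `D` (letter positions) and
#'   `degrees`.
#' @examples
#' cm <- confusion_matrix(c(1, 2, 3, 4), c(1, 2, 3, 4))
#' mean_distance(cm)$D # 0: perfect prediction
#' @export
mean_distance <- function(cm, gap_deg = 0.88) {
  m <- unclass(cm)
  if (any(!is.finite(m)) || any(abs(rowSums(m) - 1) > 1e-8))
    stop("confusion matrix rows must each sum to 1")
  i <- as.numeric(rownames(m)); j <- as.numeric(colnames(m))
  D <- sum(m * abs(outer(i, j, "-"))) / nrow(m)
  structure(list(D = D, degrees = D * gap_deg), class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("mean distance D = %.2f letter positions (%.2f deg)\n",
              x$D, x$degrees))
  invisible(x)
}

#' Exact binomial significance threshold for decoding accuracy
#'
#' Smallest accuracy k/n (in percent) whose exact upper-tail probability
#' P(X >= k) under X ~ Binomial(n, 1/n_classes) falls below `alpha`;
#' the tail is computed by exact summation of binomial probabilities.
#'
#' @param n Number of independent classifications.
#' @param n_classes Number of classes (chance = 1/n_classes).
#' @param alpha Significance level in (0, 1).
#' @return Threshold accuracy in percent, with the critical count in
#'   attribute `k`.
#' @examples
#' binomial_threshold(15, 4, 0.05) # 8 of 15 = 53.3%
#' @export
binomial_threshold <- function(n, n_classes = 4, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  p <- 1 / n_classes
  probs <- stats::dbinom(0:n, n, p)
  tail <- rev(cumsum(rev(probs))) # tail[k+1] = P(X >= k)
  k <- which(tail < alpha)[1] - 1L
  if (is.na(k)) k <- n + 1L # alpha smaller than P(X = n)
  structure(100 * k / n, k = k)
}

#' Permutation test of the LOSO decoding accuracy
#'
#' Permutes the location labels within each subject and re-runs the full
#' leave-one-subject-out pipeline per permutation. The p-value uses the
#' add-one convention p = (1 + #[DA_perm >= DA_obs]) / (B + 1), so it is
#' never zero.
#'
#' @param features Feature table as in [loso_cv()].
#' @param n_permutations Number of label permutations B.
#' @param seed Integer seed (mandatory source of permutation randomness).
#' @param ... Passed to [loso_cv()].
#' @return A `permutation_test`: list with `p.value`, `observed` (DA %),
#'   `perm` (B permuted DAs) and `n_permutations`.
#' @export
permutation_test <- function(features, n_permutations = 1000, seed, ...) {
  stopifnot(n_permutations >= 1)
  obs_pred <- loso_cv(features, ...)
  observed <- decoding_accuracy(obs_pred$predicted, obs_pred$location)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_permutations), function(b) {
    pf <- features
    pf$location <- stats::ave(pf$location, pf$subject,
                              FUN = function(v) v[sample.int(length(v))])
    pr <- suppressWarnings(loso_cv(pf, ...))
    decoding_accuracy(pr$predicted, pr$location)
  }, numeric(1))
  structure(list(p.value = (1 + sum(perm >= observed)) / (n_permutations + 1),
                 observed = observed, perm = perm,
                 n_permutations = n_permutations),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("observed DA = %.1f%%, permutation p = %.4g (B = %d)\n",
              x$observed, x$p.value, x$n_permutations))
  invisible(x)
}

#' Single-feature decoding accuracies
#'
#' Re-runs the LOSO pipeline twelve times, each time restricting the
#' classifier to a single feature column, to assess each feature's
#' individual decoding potential.
#'
#' @inheritParams loso_cv
#' @return Named numeric vector of 12 accuracies (percent).
#' @export
single_feature_da <- function(features, ...) {
  cols <- intersect(feature_names(), names(features))
  vapply(cols, function(cl) {
    pr <- loso_cv(features, feature_cols = cl, ...)
    decoding_accuracy(pr$predicted, pr$location)
  }, numeric(1))
}

#' Binary attended-vs-unattended LOSO evaluation
#'
#' Leave-one-subject-out evaluation of the binary classifier
#' ([attended_svm()]) on the target-locked feature table: overall
#' accuracy and, following the per-location analysis, accuracy restricted
#' to rows of each letter location. A location whose held-out rows carry
#' a single class is reported `NaN`.
#'
#' @param att Attended feature table (see
#'   [extract_attended_features()] / [simulate_attended_features()]).
#' @param ... Passed to [attended_svm()].
#' @return List with `overall` (DA %), `per_location` (4 DAs %), and
#'   `predictions`.
#' @export
binary_attended_eval <- function(att, ...) {
  fn <- intersect(feature_names(locks = "target"), names(att))
  subjects <- sort(unique(as.character(att$subject)))
  stopifnot(length(subjects) >= 3)
  preds <- do.call(rbind, lapply(subjects, function(s) {
    train <- att[att$subject != s, ]
    test <- att[att$subject == s, ]
    fit <- attended_svm(train[, fn], train$attended, ...)
    data.frame(subject = s, letter_location = test$letter_location,
               attended = test$attended,
               predicted = as.logical(as.character(
                 predict(fit, test[, fn]))))
  }))
  overall <- decoding_accuracy(preds$predicted, preds$attended)
  per_loc <- vapply(sort(unique(att$letter_location)), function(L) {
    d <- preds[preds$letter_location == L, ]
    if (length(unique(d$attended)) < 2) return(NaN)
    decoding_accuracy(d$predicted, d$attended)
  }, numeric(1))
  names(per_loc) <- sort(unique(att$letter_location))
  list(overall = overall, per_location = per_loc, predictions = preds)
}

#' Ocular-confound split by HEOG amplitude
#'
#' Splits subjects into a high-eye-movement group (the subjects with the
#' largest lateralized HEOG amplitudes; 5 of 15, scaled to `ceiling(n/3)`
#' for other n) and the remaining low-eye-movement group, and re-runs the
#' four-class LOSO decoding on the low-movement group alone. Ties at the
#' boundary are resolved by subject-id order.
#'
#' @param heog Named per-subject HEOG amplitude summaries (microvolts;
#'   names = subject ids matching `features$subject`).
#' @param features Feature table as in [loso_cv()].
#' @param ... Passed to [loso_cv()].
#' @return List with `group1` (high movers), `group2` (low movers), and
#'   `report` (predictions, `da`, confusion matrix for group 2).
#' @export
heog_split <- function(heog, features, ...) {
  stopifnot(!is.null(names(heog)))
  n <- length(heog)
  n1 <- if (n == 15) 5L else as.integer(ceiling(n / 3))
  if (n != 15)
    message("n = ", n, " subjects; splitting ", n1, " vs ", n - n1)
  ord <- order(-heog, names(heog))
  group1 <- sort(names(heog)[ord[seq_len(n1)]])
  group2 <- sort(setdiff(names(heog), group1))
  sub <- features[as.character(features$subject) %in% group2, ]
  preds <- loso_cv(sub, ...)
  cm <- confusion_matrix(preds$predicted, preds$location)
  list(group1 = group1, group2 = group2,
       report = list(predictions = preds,
                     da = decoding_accuracy(preds$predicted, preds$location),
                     confusion = cm))
}

#' Full decoding report for a study
#'
#' Runs the complete evaluation: LOSO predictions, decoding accuracy
#' (overall, per location, and the per-subject majority-correct tally),
#' row-normalized confusion matrix, mean letter-position distance with
#' visual-angle conversion, exact binomial significance thresholds for
#' the subject count, single-feature accuracies, and (optionally) the
#' permutation test, binary attended evaluation and HEOG confound split.
#'
#' @param features Feature table as in [loso_cv()].
#' @param n_permutations If > 0, run [permutation_test()] with this many
#'   permutations.
#' @param seed Seed for the permutation test.
#' @param attended Optional attended feature table for
#'   [binary_attended_eval()].
#' @param heog Optional named HEOG summaries for [heog_split()].
#' @param gap_deg Horizontal letter spacing in degrees.
#' @param single_features Compute the 12 single-feature accuracies?
#' @param ... Passed to [loso_cv()].
#' @return An object of class `decoding_report`.
#' @export
decode_study <- function(features, n_permutations = 0, seed = 1L,
                         attended = NULL, heog = NULL, gap_deg = 0.88,
                         single_features = TRUE, ...) {
  preds <- loso_cv(features, ...)
  da <- decoding_accuracy(preds$predicted, preds$location)
  cm <- confusion_matrix(preds$predicted, preds$location)
  n_subj <- length(unique(preds$subject))
  # per-subject accounting: a subject counts as correct when the majority
  # (> half) of its location rows are correctly classified
  subj_correct <- vapply(split(preds, preds$subject), function(d)
    mean(d$predicted == d$location) > 0.5, logical(1))
  report <- list(
    predictions = preds,
    da = da,
    da_display = format_da(da),
    per_location = 100 * diag(unclass(cm)),
    subject_majority_pct = 100 * mean(subj_correct),
    confusion = cm,
    distance = mean_distance(cm, gap_deg),
    binomial_thresholds = c(
      `0.05` = as.numeric(binomial_threshold(n_subj, 4, 0.05)),
      `0.01` = as.numeric(binomial_threshold(n_subj, 4, 0.01))),
    n_subjects = n_subj,
    n_folds = attr(preds, "n_folds")
  )
  if (single_features)
    report$single_feature_da <- single_feature_da(features, ...)
  if (n_permutations > 0)
    report$permutation <- permutation_test(features, n_permutations, seed, ...)
  if (!is.null(attended))
    report$binary <- binary_attended_eval(attended)
  if (!is.null(heog))
    report$heog <- heog_split(heog, features, ...)
  structure(report, class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat("Four-class decoding report (", x$n_subjects, " subjects, ",
      x$n_folds, " LOSO folds)\n", sep = "")
  cat(sprintf("  decoding accuracy: %d%% (%.2f%%; chance 25%%)\n",
              x$da_display, x$da))
  cat(sprintf("  per-subject majority-correct: %.0f%%\n",
              x$subject_majority_pct))
  print(x$confusion)
  print(x$distance)
  cat(sprintf("  binomial thresholds: %.1f%% (p<.05), %.1f%% (p<.01)\n",
              x$binomial_thresholds[["0.05"]],
              x$binomial_thresholds[["0.01"]]))
  if (!is.null(x$permutation)) print(x$permutation)
  if (!is.null(x$binary))
    cat(sprintf("  binary attended DA: %.1f%% (per location: %s)\n",
                x$binary$overall,
                paste(sprintf("%.0f%%", x$binary$per_location),
                      collapse = ", ")))
  if (!is.null(x$heog))
    cat(sprintf("  low-HEOG subgroup (n = %d) DA: %.1f%%\n",
                length(x$heog$group2), x$heog$report$da))
  invisible(x)
}

#' @export
summary.decoding_report <- function(object, ...) print(object, ...)
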