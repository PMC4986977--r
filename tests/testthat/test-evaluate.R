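test_that("LOSO-CV produces one fold per subject and is order-invariant", {
  ft <- simulate_features(15, effect_uv = 1, noise_sd_uv = 0.4, seed = 1)
  pr <- loso_cv(ft)
  expect_equal(attr(pr, "n_folds"), 15)
  expect_equal(nrow(pr), 60)

  ft3 <- simulate_features(3, effect_uv = 1, noise_sd_uv = 0.4, seed = 2)
  expect_equal(attr(loso_cv(ft3), "n_folds"), 3)
  expect_error(loso_cv(simulate_features(2, seed = 1)), "at least 3")

  # shuffling rows does not change the predictions
  set.seed(3)
  shuffled <- ft[sample(nrow(ft)), ]
  a <- loso_cv(shuffled)
  b <- loso_cv(ft)
  a <- a[order(a$subject, a$location), ]
  b <- b[order(b$subject, b$location), ]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("subjects with missing location rows are excluded before folding", {
  ft <- simulate_features(5, effect_uv = 1, noise_sd_uv = 0.4, seed = 4)
  ft <- ft[!(ft$subject == 2 & ft$location == 3), ]
  expect_warning(pr <- loso_cv(ft), "missing locations")
  expect_equal(attr(pr, "n_folds"), 4)
})

test_that("decoding accuracy follows the 10-of-15 display convention", {
  pred <- c(rep(1, 10), rep(2, 5))
  truth <- rep(1, 15)
  da <- decoding_accuracy(pred, truth)
  expect_equal(da, 100 * 10 / 15)
  expect_equal(format_da(da), 66)
  expect_equal(decoding_accuracy(1:4, 1:4), 100)
  expect_error(decoding_accuracy(integer(0), integer(0)), "empty")
})

test_that("uniform random guessing converges to 25% chance", {
  set.seed(123)
  n <- 100000
  da <- decoding_accuracy(sample(1:4, n, TRUE), sample(1:4, n, TRUE))
  expect_lt(abs(da - 25), 0.5)
})

test_that("confusion matrices are row-normalized and match a counting oracle", {
  cmp <- confusion_matrix(1:4, 1:4)
  expect_equal(unclass(cmp), diag(4), ignore_attr = TRUE)

  cm1 <- confusion_matrix(rep(1, 8), rep(1:4, 2))
  expect_equal(unname(unclass(cm1)[, 1]), rep(1, 4))

  set.seed(5)
  truth <- sample(1:4, 200, TRUE)
  pred <- sample(1:4, 200, TRUE)
  cm <- unclass(confusion_matrix(pred, truth))
  for (i in 1:4) for (j in 1:4)
    expect_equal(cm[i, j], sum(pred == j & truth == i) / sum(truth == i))
  expect_equal(unname(rowSums(cm)), rep(1, 4))

  und <- confusion_matrix(c(1, 2), c(1, 2), levels = 1:4)
  expect_equal(attr(und, "undefined_rows"), 3:4)
})

test_that("mean distance D matches brute-force summation and the degree conversion", {
  expect_equal(mean_distance(confusion_matrix(1:4, 1:4))$D, 0)

  uni <- structure(matrix(0.25, 4, 4, dimnames = list(1:4, 1:4)),
                   class = "confusion_matrix")
  expect_equal(mean_distance(uni)$D, 1.25)

  anti <- structure(diag(4)[4:1, ], dimnames = list(1:4, 1:4),
                    class = "confusion_matrix")
  expect_equal(mean_distance(anti)$D, 2.0)

  # the published distance-to-degrees conversion
  expect_equal(round(0.62 * 0.88, 2), 0.55)

  bad <- structure(matrix(0.3, 4, 4, dimnames = list(1:4, 1:4)),
                   class = "confusion_matrix")
  expect_error(mean_distance(bad), "sum to 1")

  # oracle equivalence on 1,000 random row-stochastic matrices
  set.seed(6)
  for (r in 1:1000) {
    m <- matrix(rexp(16), 4, 4)
    m <- m / rowSums(m)
    dimnames(m) <- list(1:4, 1:4)
    D <- mean_distance(structure(m, class = "confusion_matrix"))$D
    acc <- 0
    for (i in 1:4) for (j in 1:4) acc <- acc + m[i, j] * abs(i - j)
    expect_equal(D, acc / 4)
  }
})

test_that("binomial thresholds come from exact tail sums and are monotone", {
  for (n in c(10, 15, 60)) for (alpha in c(0.05, 0.01)) {
    th <- binomial_threshold(n, 4, alpha)
    k <- attr(th, "k")
    # independent oracle via the exact binomial upper tail
    tail_p <- function(k) stats::pbinom(k - 1, n, 0.25, lower.tail = FALSE)
    expect_lt(tail_p(k), alpha)
    expect_gte(tail_p(k - 1), alpha)
    expect_equal(as.numeric(th), 100 * k / n)
  }
  expect_gte(binomial_threshold(15, 4, 0.01), binomial_threshold(15, 4, 0.05))
  # the n = 15 study: 8 of 15 correct is the p < .05 criterion
  expect_equal(attr(binomial_threshold(15, 4, 0.05), "k"), 8L)
})

test_that("permutation p-values respect the add-one bounds and tie to 1 for label-invariant data", {
  ft <- simulate_features(6, effect_uv = 2, noise_sd_uv = 0.2, seed = 7)
  pt <- permutation_test(ft, n_permutations = 19, seed = 8)
  expect_gte(pt$p.value, 1 / 20)
  expect_lte(pt$p.value, 1)
  expect_equal(length(pt$perm), 19)

  # all-zero features: predictions cannot depend on the labels -> p = 1
  ft0 <- ft
  ft0[, feature_names()] <- 0
  pt0 <- permutation_test(ft0, n_permutations = 19, seed = 9)
  expect_equal(pt0$p.value, 1)
})

test_that("single-feature decoding isolates the informative feature", {
  ft <- simulate_features(8, effect_uv = 0, noise_sd_uv = 0.3, seed = 10)
  mu <- c(1.5, 1, -1, -1.5)
  ft$cue_O1_O2_late <- mu[ft$location] + rnorm(nrow(ft), sd = 0.2)
  sf <- single_feature_da(ft)
  expect_equal(length(sf), 12)
  expect_equal(names(which.max(sf)), "cue_O1_O2_late")
})

test_that("single-feature accuracies sit in the chance band on pure noise", {
  ft0 <- simulate_features(15, effect_uv = 0, noise_sd_uv = 0.3, seed = 1)
  sf <- single_feature_da(ft0)
  lo <- 100 * stats::qbinom(0.025, 60, 0.25) / 60
  hi <- 100 * stats::qbinom(0.975, 60, 0.25) / 60
  expect_true(all(sf >= lo & sf <= hi))
})

test_that("binary attended evaluation reports overall and per-location accuracy", {
  att <- simulate_attended_features(10, effect_uv = 1, noise_sd_uv = 0.3,
                                    seed = 11)
  be <- binary_attended_eval(att)
  expect_gt(be$overall, 90)
  expect_equal(length(be$per_location), 4)
  expect_true(all(be$per_location > 70))

  att0 <- simulate_attended_features(10, effect_uv = 0, noise_sd_uv = 0.3,
                                     seed = 12)
  be0 <- binary_attended_eval(att0)
  n <- nrow(att0)
  lo <- 100 * stats::qbinom(0.025, n, 0.5) / n
  hi <- 100 * stats::qbinom(0.975, n, 0.5) / n
  expect_gte(be0$overall, lo)
  expect_lte(be0$overall, hi)
})

test_that("the HEOG confound split takes the 5 largest movers of 15", {
  heog <- stats::setNames(1:15 / 10, sprintf("S%02d", 1:15))
  ft <- simulate_features(15, effect_uv = 1, noise_sd_uv = 0.4, seed = 13)
  ft$subject <- sprintf("S%02d", ft$subject)
  hs <- heog_split(heog, ft)
  expect_equal(hs$group1, sprintf("S%02d", 11:15))
  expect_equal(hs$group2, sprintf("S%02d", 1:10))
  expect_equal(attr(hs$report$predictions, "n_folds"), 10)
  expect_gt(hs$report$da, 80)

  # boundary ties resolved by subject-id order
  heog_t <- stats::setNames(c(rep(1, 6), rep(2, 9)), sprintf("S%02d", 1:15))
  hs_t <- heog_split(heog_t, ft)
  expect_equal(hs_t$group1, sprintf("S%02d", 7:11))

  # n != 15 scales the split and logs it
  ft9 <- simulate_features(9, effect_uv = 1, noise_sd_uv = 0.4, seed = 14)
  heog9 <- stats::setNames(seq_len(9), 1:9)
  expect_message(hs9 <- heog_split(heog9, ft9), "splitting")
  expect_equal(length(hs9$group1), 3)
})

test_that("overall DA equals the confusion-matrix diagonal mean under one prediction per cell", {
  ft <- simulate_features(12, effect_uv = 0.8, noise_sd_uv = 0.8, seed = 15)
  pr <- loso_cv(ft)
  da <- decoding_accuracy(pr$predicted, pr$location)
  cm <- confusion_matrix(pr$predicted, pr$location, levels = 1:4)
  expect_equal(da, 100 * mean(diag(unclass(cm))))
})

test_that("decode_study assembles a coherent report", {
  ft <- simulate_features(8, effect_uv = 1, noise_sd_uv = 0.4, seed = 16)
  att <- simulate_attended_features(8, effect_uv = 1, noise_sd_uv = 0.4,
                                    seed = 17)
  heog <- stats::setNames(runif(8), sort(unique(ft$subject)))
  rep <- decode_study(ft, n_permutations = 9, seed = 18, attended = att,
                      heog = heog)
  expect_s3_class(rep, "decoding_report")
  expect_equal(rep$n_folds, 8)
  expect_equal(rep$da_display, format_da(rep$da))
  expect_equal(length(rep$single_feature_da), 12)
  expect_equal(length(rep$per_location), 4)
  expect_true(rep$permutation$p.value <= 1)
  expect_output(print(rep), "decoding accuracy")
})
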