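fs <- 512

test_that("band-pass filtering removes DC, passes the band, and stops 50 Hz", {
  # long signal so the slow 0.1 Hz high-pass transients die out well before
  # the analysed interior
  t <- seq(0, 60, by = 1 / fs)
  interior <- seq(round(length(t) * 0.35), round(length(t) * 0.65))

  # constant signal attenuated to ~0
  y <- bandpass_filter(rep(10, length(t)), 0.1, 30, fs)
  expect_lt(max(abs(y[interior])), 0.05)

  # 5 Hz passed at ~unit gain with zero phase shift
  x5 <- sin(2 * pi * 5 * t)
  y5 <- bandpass_filter(x5, 0.1, 30, fs)
  expect_equal(max(abs(y5[interior])), 1, tolerance = 0.01)
  cc <- stats::ccf(y5[interior], x5[interior], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 50 Hz attenuated by the two-pass magnitude response of the design
  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass_filter(x50, 0.1, 30, fs)
  lp <- signal::butter(4, 30 / (fs / 2), type = "low")
  h <- signal::freqz(lp, Fs = fs)
  gain_oracle <- abs(h$h[which.min(abs(h$f - 50))])^2 # forward + backward
  expect_equal(max(abs(y50[interior])), gain_oracle,
               tolerance = 0.1 * gain_oracle)
})

test_that("filtering is idempotent in the pass band", {
  t <- seq(0, 60, by = 1 / fs)
  interior <- seq(round(length(t) * 0.35), round(length(t) * 0.65))
  x <- sin(2 * pi * 8 * t)
  once <- bandpass_filter(x, 0.1, 30, fs)
  twice <- bandpass_filter(once, 0.1, 30, fs)
  expect_lt(abs(max(abs(twice[interior])) - max(abs(once[interior]))) /
              max(abs(once[interior])), 0.01)
})

test_that("bands outside Nyquist are rejected", {
  expect_error(bandpass_filter(rnorm(100), 0.1, 300, fs), "Nyquist")
  expect_error(bandpass_filter(rnorm(100), 30, 0.1, fs), "Nyquist")
})

test_that("mastoid re-referencing subtracts the mastoid average from EEG only", {
  n <- 1000
  data <- matrix(0, n, 10)
  rec <- make_recording(data)
  # zero mastoids: identity
  rec$data[, "PO7"] <- 1.5
  expect_identical(rereference(rec)$data, rec$data)
  # constant mastoids 2 and 4 uV: every EEG sample reduced by 3
  rec$data[, "M1"] <- 2; rec$data[, "M2"] <- 4
  rec$data[, "VEOG"] <- 7
  out <- rereference(rec)
  expect_equal(out$data[, "PO7"], rep(1.5 - 3, n))
  expect_equal(out$data[, "O2"], rep(-3, n))
  expect_equal(out$data[, "VEOG"], rep(7, n)) # EOG untouched
  # random mastoids: brute-force recomputation matches
  set.seed(1)
  rec$data[] <- rnorm(length(rec$data))
  out <- rereference(rec)
  ref <- (rec$data[, "M1"] + rec$data[, "M2"]) / 2
  for (ch in c("PO7", "PO8", "O1", "O2", "PO3", "PO4"))
    expect_equal(out$data[, ch], rec$data[, ch] - ref)
})

test_that("re-referencing requires mastoid channels", {
  rec <- make_recording(matrix(0, 100, 10))
  colnames(rec$data)[9] <- "Mx"
  expect_error(rereference(rec), "mastoid")
})

test_that("epoching cuts 512-sample windows and baseline-corrects them", {
  n <- 4000
  data <- matrix(5, n, 10) # constant 5 uV everywhere
  events <- data.frame(sample = c(600, 2000), kind = "cue",
                       location = c(1L, 2L), cued = c(1L, 2L))
  rec <- make_recording(data, events = events)
  ep <- epoch_recording(rec, "cue")
  expect_equal(dim(ep$data), c(2, 10, round(1.0 * fs)))
  expect_equal(max(abs(ep$data)), 0) # constant removed by baseline
  # baseline mean is zero by definition
  pre <- ep$times < 0
  expect_equal(max(abs(apply(ep$data[, , pre], c(1, 2), mean))), 0)
})

test_that("a linear ramp epochs to its closed form", {
  n <- 4000
  a <- 0.01 # uV per sample
  data <- matrix(rep(a * seq_len(n), 10), n, 10)
  events <- data.frame(sample = 1000L, kind = "cue", location = 1L, cued = 1L)
  rec <- make_recording(data, events = events)
  ep <- epoch_recording(rec, "cue")
  n_pre <- round(0.2 * fs)
  samp <- 1000L - n_pre + seq_len(round(fs)) - 1L
  expected <- a * samp - mean(a * samp[seq_len(n_pre)])
  expect_equal(as.numeric(ep$data[1, "PO7", ]), expected, tolerance = 1e-12)
})

test_that("events too close to the recording edge are dropped with a warning", {
  rec <- make_recording(matrix(0, 1000, 10),
                        events = data.frame(sample = c(50L, 500L), kind = "cue",
                                            location = 1L, cued = 1L))
  expect_warning(ep <- epoch_recording(rec, "cue"), "edge")
  expect_equal(nrow(ep$info), 1)
})

test_that("artifact rejection applies the blink, eye-movement and absolute rules in order", {
  arr <- zero_epoch_array(4)
  # epoch 2: EEG sample at +120 uV -> absolute limit
  arr[2, "PO3", 300] <- 120
  # epoch 3: VEOG 60 uV step within 100 ms -> blink
  arr[3, "VEOG", 250:300] <- 60
  # epoch 4: HEOG 30 uV drift over 600 ms (~307 samples) -> kept
  arr[4, "HEOG", 101:408] <- 30 * seq(0, 1, length.out = 308)
  ep <- reject_artifacts(make_epochs(arr))
  expect_equal(ep$info$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(ep$info$reason[2], "absolute limit")
  expect_equal(ep$info$reason[3], "blink")
  # epoch counts are conserved
  expect_equal(sum(ep$info$kept) + sum(!ep$info$kept), 4)
})

test_that("rejection thresholds are strict and EOG is exempt from the absolute rule", {
  arr <- zero_epoch_array(2)
  arr[1, "VEOG", 200:250] <- 50 # exactly 50 uV: not > 50
  arr[2, "VEOG", 200:250] <- 120 # VEOG above 100 uV but EOG exempt...
  ep <- reject_artifacts(make_epochs(arr))
  expect_true(ep$info$kept[1])
  expect_false(ep$info$kept[2]) # ...rejected as a blink, not absolute limit
  expect_equal(ep$info$reason[2], "blink")
})

test_that("sliding peak-to-peak matches the exhaustive window oracle", {
  set.seed(42)
  for (r in 1:20) {
    x <- cumsum(rnorm(400))
    w <- sample(10:150, 1)
    expect_equal(erpdecode:::sliding_p2p_max(x, w), p2p_oracle(x, w))
  }
})

test_that("rejection recall is perfect on injected supra-threshold artifacts", {
  sch <- generate_schedule(small_design(12), seed = 2)
  rec <- synthesize_subject(sch, ground_truth(noise_sd_uv = 3,
                                              eog_noise_sd_uv = 1.5), seed = 3)
  inj <- inject_artifacts(rec, rates = c(blink = 0.4, saccade = 0.4), seed = 7,
                          blink_amp_uv = 120, saccade_amp_uv = 80)
  prep <- preprocess_subject(inj$recording)
  fs <- rec$fs
  for (ep in list(prep$cue, prep$target)) {
    n_pre <- round(0.2 * fs); n_total <- round(1.0 * fs)
    starts <- ep$info$sample - n_pre
    ends <- starts + n_total - 1L
    for (i in seq_len(nrow(inj$log))) {
      a <- inj$log$sample[i]
      dur <- if (inj$log$kind[i] == "blink") 0.2 else 0.53
      b <- a + round(dur * fs)
      hit <- which(starts <= a & ends >= b) # epochs containing the template
      expect_true(all(!ep$info$kept[hit]))
    }
  }
  # with artifacts off and modest noise: no rejections
  prep0 <- preprocess_subject(rec)
  expect_equal(prep0$rejection_rate, 0)
})

test_that("subjects are excluded at the 30% rejection-rate criterion", {
  kept <- suppressMessages(exclude_subjects(c(a = 0.05, b = 0.10, c = 0.30)))
  expect_equal(kept, c("a", "b"))
  expect_equal(suppressMessages(exclude_subjects(rep(0, 4))),
               as.character(1:4))
  rates16 <- stats::setNames(c(rep(0.05, 15), 0.30), paste0("S", 1:16))
  expect_equal(length(suppressMessages(exclude_subjects(rates16))), 15)
  expect_error(suppressMessages(exclude_subjects(c(0.5, 0.9))), "all subjects")
})
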