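test_that("segmentation produces non-overlapping full windows, dropping the tail", {
  rec <- eeg_recording(matrix(rnorm(2 * 12000), 2), 200)
  segs <- segment_signal(rec, 1)
  expect_length(segs, 60L)
  expect_true(all(vapply(segs, ncol, 1L) == 200L))

  rec4 <- eeg_recording(matrix(rnorm(2 * 8 * 200), 2), 200)
  expect_length(segment_signal(rec4, 4), 2L)

  rec_short <- eeg_recording(matrix(rnorm(2 * 300), 2), 200)  # 1.5 s
  expect_length(segment_signal(rec_short, 1), 1L)

  rec_tiny <- eeg_recording(matrix(rnorm(2 * 100), 2), 200)   # 0.5 s
  expect_warning(out <- segment_signal(rec_tiny, 1), "shorter")
  expect_length(out, 0L)
})

test_that("band-pass filter passes in-band and rejects out-of-band tones", {
  fs <- 200
  t <- seq(0, 5, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  inband <- bandpass_filter(tone, 8, 12, fs)
  expect_gte(mean(inband^2), 0.9 * mean(tone^2))
  outband <- bandpass_filter(tone, 30, 64, fs)
  expect_lte(mean(outband^2), 0.01 * mean(tone^2))
  expect_equal(bandpass_filter(rep(0, 1000), 8, 12, fs), rep(0, 1000))
  expect_error(bandpass_filter(tone, 30, 110, fs), "Nyquist")
})

test_that("differential entropy matches the Gaussian closed form", {
  expect_equal(differential_entropy(c(-1, 1) * sqrt(1 / (2 * pi * exp(1)))), 0,
               tolerance = 1e-9)
  # population variance of c(-1, 1) is exactly 1
  expect_equal(differential_entropy(c(-1, 1)), 0.5 * (1 + log(2 * pi)),
               tolerance = 1e-9)
  set.seed(7)
  x <- rnorm(200000, sd = 2)
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1) * 4),
               tolerance = 0.01)
  expect_error(differential_entropy(rep(1, 10)), "variance")
  expect_error(differential_entropy(1), "2 samples")
})

test_that("scaling a signal by k adds log(k) to every DE value", {
  set.seed(1)
  x <- rnorm(500)
  for (k in c(0.1, 2, 37.5)) {
    expect_equal(differential_entropy(k * x),
                 differential_entropy(x) + log(k), tolerance = 1e-6)
  }
})

test_that("extracted features have segments x channels x bands layout", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(62 * 5 * 200), 62), 200, label = 1L)
  fs <- extract_features(rec, window = 1)
  expect_equal(dim(fs$features), c(5L, 62L, 5L))
  expect_true(all(is.finite(fs$features)))
  expect_equal(fs$labels, rep(1L, 5L))
})

test_that("moving-average smoothing with k = 1 is the identity", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(4 * 6 * 200), 4), 200)
  a <- extract_features(rec, smoothing = "none")
  b <- extract_features(rec, smoothing = "moving_average", k = 1L)
  expect_identical(a$features, b$features)
})

test_that("wider bands of white noise carry more differential entropy", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(2 * 60 * 200), 2), 200)
  fs <- extract_features(rec)
  de <- colMeans(fs$features[, 1, ])       # mean over segments, channel 1
  names(de) <- fs$band_names
  expect_gt(de["gamma"], de["beta"])       # 34 Hz vs 18 Hz wide
  expect_gt(de["beta"], de["alpha"])       # 18 Hz vs 4 Hz
  expect_gt(de["theta"], de["delta"])      # 4 Hz vs 3 Hz
})

test_that("segment counts are conserved when trials are combined", {
  spec <- tiny_spec(segments_per_trial = 7L)
  g <- generate_recording(spec)
  per_trial <- lapply(g$recordings, extract_features)
  combined <- bind_featuresets(per_trial)
  expect_equal(dim(combined$features)[1],
               sum(vapply(per_trial, function(f) dim(f$features)[1], 1L)))
  expect_equal(sort(unique(combined$trial_index)),
               sort(unique(g$truth$trials$trial)))
})
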