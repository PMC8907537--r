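test_that("generation is bitwise reproducible for a fixed spec and seed", {
  spec <- tiny_spec(seed = 42L)
  r1 <- generate_recording(spec)
  r2 <- generate_recording(spec)
  expect_identical(r1$recordings[[3]]$signal, r2$recordings[[3]]$signal)
  f1 <- generate_featureset(spec)
  f2 <- generate_featureset(spec)
  expect_identical(f1$featureset$features, f2$featureset$features)
})

test_that("identity class graph yields mutually uncorrelated channels", {
  spec <- synthetic_spec(n_channels = 8L, n_classes = 1L,
                         trials_per_class_per_subject = 1L,
                         segments_per_trial = 60L,
                         class_graphs = list(diag(8)),
                         band_powers = default_band_powers(1), seed = 13)
  rec <- generate_recording(spec)$recordings[[1]]
  W <- pcc_adjacency(rec)$weights
  expect_lt(mean(W[upper.tri(W)]), 0.1)
})

test_that("a unit-weight edge in the class graph forces near-perfect correlation", {
  G <- diag(8); G[1, 2] <- G[2, 1] <- 1
  spec <- synthetic_spec(n_channels = 8L, n_classes = 1L,
                         trials_per_class_per_subject = 1L,
                         segments_per_trial = 60L, class_graphs = list(G),
                         band_powers = default_band_powers(1), seed = 14)
  rec <- generate_recording(spec)$recordings[[1]]
  expect_gt(abs(cor(rec$signal[1, ], rec$signal[2, ])), 0.9)
})

test_that("trial layout matches the requested session shape", {
  # 4 classes x 6 trials each = 24 trials, the 4-emotion session shape
  spec <- synthetic_spec(n_channels = 12L, n_classes = 4L,
                         trials_per_class_per_subject = 6L,
                         segments_per_trial = 2L,
                         class_graphs = replicate(4, diag(12), simplify = FALSE),
                         band_powers = default_band_powers(4), seed = 15)
  g <- generate_featureset(spec)
  tt <- g$truth$trials
  expect_equal(nrow(tt), 24L)
  expect_equal(as.vector(table(tt$class)), rep(6L, 4L))
  # every segment maps to exactly one (subject, trial, class)
  fs <- g$featureset
  seg_class <- tapply(fs$labels, fs$trial_index, unique)
  expect_true(all(lengths(seg_class) == 1L))
})

test_that("single-class generation yields constant labels", {
  spec <- synthetic_spec(n_channels = 6L, n_classes = 1L,
                         trials_per_class_per_subject = 2L,
                         segments_per_trial = 3L, class_graphs = list(diag(6)),
                         band_powers = default_band_powers(1), seed = 16)
  fs <- generate_featureset(spec)$featureset
  expect_equal(unique(fs$labels), 0L)
})

test_that("classes with distinct band powers are linearly separable above chance", {
  spec <- tiny_spec(n_classes = 2L, trials_per_class = 4L,
                    segments_per_trial = 20L, seed = 17)
  fs <- generate_featureset(spec)$featureset
  X <- matrix(fs$features, nrow = dim(fs$features)[1])
  y <- fs$labels
  # nearest-centroid reference classifier, split by even/odd segments
  tr <- seq_along(y) %% 2L == 0L
  mu0 <- colMeans(X[tr & y == 0L, ]); mu1 <- colMeans(X[tr & y == 1L, ])
  pred <- apply(X[!tr, ], 1L, function(r) {
    as.integer(sum((r - mu1)^2) < sum((r - mu0)^2))
  })
  expect_gt(mean(pred == y[!tr]), 0.8)   # chance = 0.5
})

test_that("nearest-PSD repair returns a unit-diagonal PSD correlation matrix", {
  C <- matrix(0.9, 4, 4); diag(C) <- 1
  C[1, 2] <- C[2, 1] <- -0.95                 # makes the matrix indefinite
  R <- nearest_psd(C)
  expect_equal(diag(R), rep(1, 4))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_channels = 4L, n_classes = 1L,
                              class_graphs = list(matrix(2, 4, 4))))
  expect_error(synthetic_spec(n_channels = 4L, n_classes = 1L,
                              class_graphs = list(diag(4)),
                              band_powers = matrix(-1, 1, 5)))
})
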