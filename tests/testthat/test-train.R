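test_that("cross-entropy loss has its closed-form values", {
  perfect <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(loss_cross_entropy(perfect, c(0L, 1L)), 0, tolerance = 1e-9)
  uniform <- matrix(1 / 3, 2, 3)
  expect_equal(loss_cross_entropy(uniform, c(0L, 2L)), log(3),
               tolerance = 1e-9)
  # zero parameters contribute nothing to the penalty
  expect_equal(loss_cross_entropy(uniform, c(0L, 2L),
                                  tensors = list(W = matrix(0, 4, 4)),
                                  alpha = 0.01),
               log(3), tolerance = 1e-12)
  expect_error(loss_cross_entropy(uniform, c(0L, 3L)), "range")
})

test_that("Adam leaves parameters unchanged at zero gradient and takes
           lr-sized first steps", {
  p <- c(1.5, -2)
  st <- adam_init(p)
  up <- adam_step(p, c(0, 0), st, lr = 0.01)
  expect_equal(as.numeric(up$param), p)
  for (g in c(3, -0.002, 17)) {
    up1 <- adam_step(0.5, g, adam_init(0.5), lr = 0.005)
    expect_equal(abs(as.numeric(up1$param) - 0.5), 0.005, tolerance = 1e-5)
    expect_equal(sign(0.5 - as.numeric(up1$param)), sign(g))
  }
  expect_error(adam_step(1, NaN, adam_init(1), lr = 0.01), "non-finite")
})

test_that("trial-based splits follow the first-k protocol and are disjoint", {
  spec <- tiny_spec(trials_per_class = 5L)        # 15 trials
  fs <- generate_featureset(spec)$featureset
  sp <- split_trials(fs, 9)
  expect_setequal(unique(sp$train$trial_index), 1:9)
  expect_setequal(unique(sp$test$trial_index), 10:15)
  expect_length(intersect(unique(sp$train$trial_index),
                          unique(sp$test$trial_index)), 0L)
  spec4 <- synthetic_spec(n_channels = 12L, n_classes = 4L,
                          trials_per_class_per_subject = 6L,
                          segments_per_trial = 2L,
                          class_graphs = replicate(4, diag(12), simplify = FALSE),
                          seed = 3)
  sp4 <- split_trials(generate_featureset(spec4)$featureset, 16)
  expect_length(unique(sp4$test$trial_index), 8L)
  expect_error(split_trials(fs, 20), "trials")
})

test_that("zero training epochs return the initialized parameters", {
  spec <- tiny_spec(seed = 8L)
  fs <- generate_featureset(spec)$featureset
  f1 <- dgcn_fit(fs, dgcn_control(epochs = 0L, seed = 4))
  f2 <- dgcn_fit(fs, dgcn_control(epochs = 0L, seed = 4))
  expect_identical(f1$params$tensors, f2$params$tensors)
  expect_equal(nrow(f1$history), 0L)
})

test_that("training is reproducible: same config and seed, same history", {
  spec <- tiny_spec(seed = 9L, segments_per_trial = 8L)
  fs <- generate_featureset(spec)$featureset
  ctl <- dgcn_control(epochs = 3L, batch_size = 8L, seed = 5)
  f1 <- dgcn_fit(fs, ctl)
  f2 <- dgcn_fit(fs, ctl)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params$tensors$A, f2$params$tensors$A)
})

test_that("overwhelming regularization collapses weights and accuracy to chance", {
  spec <- tiny_spec(seed = 10L, segments_per_trial = 10L)
  fs <- generate_featureset(spec)$featureset
  init <- dgcn_fit(fs, dgcn_control(epochs = 0L, seed = 6))
  heavy <- dgcn_fit(fs, dgcn_control(epochs = 8L, batch_size = 16L,
                                     l2_alpha = 1000, seed = 6))
  expect_lt(sqrt(sum(heavy$params$tensors$fc1_W^2)),
            sqrt(sum(init$params$tensors$fc1_W^2)))
  final_acc <- heavy$history$accuracy[nrow(heavy$history)]
  expect_lt(abs(final_acc - 1 / 3), 0.2)
})

test_that("evaluation produces a consistent confusion matrix", {
  spec <- tiny_spec(seed = 11L, segments_per_trial = 6L)
  fs <- generate_featureset(spec)$featureset
  fit <- dgcn_fit(fs, dgcn_control(epochs = 1L, batch_size = 12L, seed = 7))
  ev <- evaluate_model(fit, fs)
  expect_equal(sum(ev$confusion), length(fs$labels))
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.integer(table(factor(fs$labels, levels = 0:2)))))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  # accuracy of an always-predict-k rule on a balanced set is 1/C
  pred0 <- rep(0L, length(fs$labels))
  expect_equal(mean(pred0 == fs$labels), 1 / 3)
})

test_that("subject summaries average per-subject accuracies", {
  expect_equal(subject_summary(c(0.9, 1.0)), c(mean = 0.95, sd = sd(c(0.9, 1))))
  expect_equal(subject_summary(rep(0.8, 4))[["sd"]], 0)
  expect_equal(subject_summary(0.7), c(mean = 0.7, sd = 0))
})

test_that("analytic gradients match central finite differences on a toy model", {
  set.seed(42)
  n <- 4; f <- 5; C <- 3; N <- 6
  params <- model_init(n, f, C, random_adjacency(n, seed = 7), dropout = 0,
                       seed = 11)
  X <- array(rnorm(N * n * f), c(N, n, f))
  y <- sample(0:(C - 1), N, replace = TRUE)
  lg <- model_loss_grad(params, X, y, alpha = 0.01)
  max_rel <- 0
  for (nm in names(params$tensors)) {
    tvec <- params$tensors[[nm]]
    idx <- sort(sample.int(length(tvec), min(length(tvec), 5L)))
    for (i in idx) {
      eps <- 1e-6 * max(1, abs(tvec[i]))
      p1 <- params; p1$tensors[[nm]][i] <- p1$tensors[[nm]][i] + eps
      p2 <- params; p2$tensors[[nm]][i] <- p2$tensors[[nm]][i] - eps
      fd <- (model_loss_grad(p1, X, y, alpha = 0.01)$loss -
               model_loss_grad(p2, X, y, alpha = 0.01)$loss) / (2 * eps)
      an <- lg$grads[[nm]][i]
      max_rel <- max(max_rel, abs(fd - an) / max(1e-6, abs(fd), abs(an)))
    }
  }
  expect_lt(max_rel, 1e-4)
})

test_that("predict returns labels or normalized probabilities", {
  spec <- tiny_spec(seed = 12L)
  fs <- generate_featureset(spec)$featureset
  fit <- dgcn_fit(fs, dgcn_control(epochs = 1L, batch_size = 12L, seed = 8))
  pr <- predict(fit, fs, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  cl <- predict(fit, fs)
  expect_true(all(cl %in% 0:2))
  expect_identical(cl, max.col(pr) - 1L)
})
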