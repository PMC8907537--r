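test_that("GCN layer reproduces hand-computed propagation", {
  # empty graph, identity weights: nonnegative features pass through
  H <- matrix(c(0.5, 2, 1, 0.1, 3, 4), 3)
  expect_equal(gcn_layer(H, matrix(0, 3, 3), diag(2)), H)
  # 2-node graph: operator is 0.5 * ones
  expect_equal(gcn_layer(matrix(c(1, 3), 2), rbind(c(0, 1), c(1, 0)),
                         matrix(1)),
               matrix(c(2, 2), 2))
})

test_that("first-order layer equals the order-1 Chebyshev filter", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    A <- random_adjacency(n, seed = rep)$weights
    X <- matrix(rnorm(n * 4), n)
    W <- matrix(rnorm(4 * 3), 4)
    theta0 <- runif(1, 0.5, 2)
    lhs <- gcn_layer(X, A, W, slope = 1, renormalize = FALSE)  # linear
    rhs <- chebyshev_filter(X, A, c(theta0, -theta0), lambda_max = 2) %*% W / theta0
    expect_lt(max(abs(lhs - rhs)), 1e-6)
  }
})

test_that("Chebyshev recurrence agrees with direct spectral filtering", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n, seed = 1000 + rep)$weights
    X <- matrix(rnorm(n * 3), n)
    K <- sample(0:5, 1)
    theta <- rnorm(K + 1)
    expect_lt(max(abs(chebyshev_filter(X, A, theta) -
                        spectral_filter(X, A, theta))), 1e-6)
  }
})

test_that("Chebyshev closed forms at K = 0 and K = 1 hold", {
  A <- random_adjacency(5, seed = 2)$weights
  X <- matrix(rnorm(15), 5)
  expect_equal(chebyshev_filter(X, A, 0.7), 0.7 * X)
  L <- eegdgcn:::.norm_laplacian(A)
  lmax <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  Lt <- (2 / lmax) * L - diag(5)
  expect_equal(chebyshev_filter(X, A, c(1, 1)), X + Lt %*% X,
               tolerance = 1e-10)
})

test_that("global add pooling sums features and ignores node order", {
  expect_equal(global_add_pool(matrix(c(5, 2), 1)), c(5, 2))
  expect_equal(global_add_pool(rbind(c(1, 2), c(3, 4))), c(4, 6))
  set.seed(22)
  H <- matrix(rnorm(40), 8)
  expect_equal(global_add_pool(H), global_add_pool(H[sample(8), ]))
})

test_that("grid reshape is row-major and invertible", {
  g <- reshape_grid(0:63)
  expect_equal(dim(g), c(8L, 8L, 1L))
  expect_equal(g[2, 1, 1], 8)           # 0-based row-major: grid[1][0] = 8
  expect_equal(unreshape_grid(g), as.numeric(0:63))
  expect_error(reshape_grid(1:10), "64")
})

test_that("SRM gates follow the sigmoid of the styled, normalized score", {
  # zero weights, identity BN: gate is exactly 0.5
  U <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  out <- srm(U, cfc_w = matrix(0, 3, 2), mode = "train")
  expect_equal(as.numeric(out), as.numeric(0.5 * U))
  # hand example: mean 4, population sd sqrt(5), weights (1, 0)
  U1 <- array(0, c(1, 1, 2, 2))
  U1[1, 1, , ] <- rbind(c(1, 3), c(5, 7))
  out1 <- srm(U1, cfc_w = matrix(c(1, 0), 1, 2),
              run_mean = 0, run_var = 1 - 1e-5, mode = "eval")
  expect_equal(attr(out1, "gates")[1, 1], plogis(4), tolerance = 1e-4)
  expect_equal(as.numeric(out1), as.numeric(plogis(4) * U1), tolerance = 1e-3)
})

test_that("SRM gates lie strictly in (0, 1) so outputs never grow", {
  set.seed(23)
  U <- array(rnorm(4 * 5 * 3 * 3), c(4, 5, 3, 3))
  out <- srm(U, cfc_w = matrix(rnorm(10), 5, 2), cfc_b = rnorm(5),
             mode = "train")
  g <- attr(out, "gates")
  expect_true(all(g > 0 & g < 1))
  expect_true(all(abs(out) <= abs(U)))
})

test_that("SRM in eval mode requires initialized running statistics", {
  U <- array(rnorm(8), c(1, 2, 2, 1))
  expect_error(srm(U, cfc_w = matrix(0, 2, 2), mode = "eval"),
               "running statistics")
})

test_that("conv stack follows the published shape chain", {
  A <- random_adjacency(6, seed = 3)
  params <- model_init(6, 5, 3, A, seed = 4)
  grid <- array(rnorm(2 * 8 * 8), c(2, 8, 8, 1))
  # intermediate shape after the first 2x2 stride-1 convolution
  c1 <- eegdgcn:::.conv2d(grid, params$tensors$conv1_K, params$tensors$conv1_b)
  expect_equal(dim(c1), c(2L, 7L, 7L, 16L))
  out <- conv_stack(grid, params, mode = "train")
  expect_equal(dim(out), c(2L, 3L, 3L, 32L))
  out1 <- conv_stack(array(rnorm(64), c(8, 8, 1)), params, mode = "train")
  expect_equal(dim(out1), c(3L, 3L, 32L))
})

test_that("an all-zero conv stack propagates zeros through the SRM", {
  A <- random_adjacency(4, seed = 5)
  params <- model_init(4, 5, 3, A, seed = 6)
  params$tensors$conv1_K[] <- 0; params$tensors$conv1_b[] <- 0
  params$tensors$conv2_K[] <- 0; params$tensors$conv2_b[] <- 0
  out <- conv_stack(array(rnorm(64), c(8, 8, 1)), params, mode = "train")
  expect_true(all(out == 0))
})

test_that("forward pass yields normalized probabilities and fused width 368", {
  A <- random_adjacency(62, seed = 7)
  params <- model_init(62, 5, 3, A, seed = 8)
  X <- array(rnorm(4 * 62 * 5), c(4, 62, 5))
  fw <- model_forward(X, params, mode = "train")
  expect_equal(rowSums(fw$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
  expect_equal(ncol(fw$fused), 368L)
  expect_equal(ncol(fw$pooled[[1]]), 16L)
  expect_equal(ncol(fw$pooled[[2]]), 64L)
})

test_that("eval-mode forward is deterministic and duplicates agree", {
  A <- random_adjacency(10, seed = 9)
  params <- model_init(10, 5, 3, A, seed = 10)
  # populate running stats with one training pass
  Xtr <- array(rnorm(6 * 10 * 5), c(6, 10, 5))
  fw <- eegdgcn:::.forward_full(params, Xtr, "train")
  params$state <- fw$new_state
  x <- matrix(rnorm(50), 10)
  X2 <- array(0, c(2, 10, 5)); X2[1, , ] <- x; X2[2, , ] <- x
  p <- model_forward(X2, params, mode = "eval")$probs
  expect_identical(p[1, ], p[2, ])
  p2 <- model_forward(X2, params, mode = "eval")$probs
  expect_identical(p, p2)
})

test_that("the graph branch is invariant to node permutation", {
  set.seed(24)
  n <- 12
  A <- random_adjacency(n, seed = 11)
  params <- model_init(n, 5, 3, A, seed = 12)
  Xtr <- array(rnorm(8 * n * 5), c(8, n, 5))
  fw <- eegdgcn:::.forward_full(params, Xtr, "train")
  params$state <- fw$new_state
  perm <- sample(n)
  params_p <- params
  params_p$tensors$A <- params$tensors$A[perm, perm]
  x <- matrix(rnorm(n * 5), n)
  X1 <- array(x, c(1, n, 5))
  Xp <- array(x[perm, ], c(1, n, 5))
  f1 <- model_forward(X1, params, mode = "eval")
  f2 <- model_forward(Xp, params_p, mode = "eval")
  expect_equal(f2$pooled[[1]], f1$pooled[[1]], tolerance = 1e-10)
  expect_equal(f2$pooled[[2]], f1$pooled[[2]], tolerance = 1e-10)
  expect_equal(f2$probs, f1$probs, tolerance = 1e-10)
})
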