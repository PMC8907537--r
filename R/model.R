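# The forward computation: multi-layer GCN with a learnable adjacency,
# global add pooling, grid reshape, two style-recalibrated conv layers,
# max pooling, multi-level feature fusion, softmax classifier.
#
# Everything is implemented in base R arrays; the batch layout for image-like
# tensors is (N, H, W, C). Backpropagation lives in backprop.R.

.lrelu <- function(x, slope) x * (x > 0) + slope * x * (x <= 0)
.lrelu_grad <- function(x, slope) (x > 0) + slope * (x <= 0)
.sigmoid <- function(x) stats::plogis(x)

#' One graph-convolution layer
#'
#' `H' = leakyReLU(P H W)` with `P` the degree-normalized propagation
#' operator of the (rectified, symmetrized, self-looped) adjacency — the
#' first-order spectral graph filter.
#'
#' @param H n x f node-feature matrix.
#' @param A n x n adjacency (matrix or [adjacency_matrix()]).
#' @param W f x f' weight matrix.
#' @param slope Leaky-ReLU negative slope (default 0.01).
#' @param renormalize Passed to [gcn_propagation()].
#' @return n x f' matrix.
#' @export
gcn_layer <- function(H, A, W, slope = 0.01, renormalize = TRUE) {
  H <- as.matrix(H); W <- as.matrix(W)
  P <- gcn_propagation(A, renormalize = renormalize)
  stopifnot(ncol(P) == nrow(H), nrow(W) == ncol(H))
  .lrelu(P %*% H %*% W, slope)
}

.norm_laplacian <- function(A) {
  A <- if (inherits(A, "eeg_adjacency")) A$weights else as.matrix(A)
  A <- abs((A + t(A)) / 2)
  d <- rowSums(A)
  if (any(d <= 0)) stop("isolated node: normalized Laplacian undefined")
  dis <- 1 / sqrt(d)
  diag(nrow(A)) - A * outer(dis, dis)
}

#' Chebyshev-polynomial graph filter
#'
#' `sum_k theta_k T_k(L~) X` with `L~ = (2 / lambda_max) L - I`, `L` the
#' symmetric normalized Laplacian of `A`, and `T_k` the Chebyshev
#' recurrence `T_k(x) = 2 x T_{k-1}(x) - T_{k-2}(x)`, `T_0 = 1`, `T_1 = x`.
#' Serves as the localized dual of [spectral_filter()]; the two must agree
#' to machine precision, and at `K = 1`, `lambda_max = 2`,
#' `theta_0 = -theta_1` the filter collapses to the first-order propagation
#' rule (see [gcn_propagation()] with `renormalize = FALSE`).
#'
#' @param X n x f signal matrix.
#' @param A n x n adjacency.
#' @param theta Numeric vector of `K + 1` Chebyshev coefficients.
#' @param lambda_max Largest Laplacian eigenvalue used for rescaling;
#'   `NULL` computes it.
#' @return Filtered n x f matrix.
#' @export
chebyshev_filter <- function(X, A, theta, lambda_max = NULL) {
  X <- as.matrix(X)
  L <- .norm_laplacian(A)
  if (is.null(lambda_max)) {
    lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  }
  stopifnot(lambda_max > 0, length(theta) >= 1L)
  Lt <- (2 / lambda_max) * L - diag(nrow(L))
  Tkm2 <- X                       # T_0 X
  out <- theta[1L] * Tkm2
  if (length(theta) >= 2L) {
    Tkm1 <- Lt %*% X              # T_1 X
    out <- out + theta[2L] * Tkm1
    k <- 3L
    while (k <= length(theta)) {
      Tk <- 2 * Lt %*% Tkm1 - Tkm2
      out <- out + theta[k] * Tk
      Tkm2 <- Tkm1; Tkm1 <- Tk
      k <- k + 1L
    }
  }
  out
}

#' Direct spectral graph filter (eigendecomposition path)
#'
#' Evaluates the same polynomial filter as [chebyshev_filter()] in the
#' spectral domain: `U g(Lambda) U^T X`, with `U, Lambda` the
#' eigendecomposition of the normalized Laplacian and
#' `g(lambda) = sum_k theta_k T_k(2 lambda / lambda_max - 1)`. Used as the
#' independent verification oracle for the localized recurrence.
#'
#' @inheritParams chebyshev_filter
#' @return Filtered n x f matrix.
#' @export
spectral_filter <- function(X, A, theta, lambda_max = NULL) {
  X <- as.matrix(X)
  L <- .norm_laplacian(A)
  e <- eigen(L, symmetric = TRUE)
  if (is.null(lambda_max)) lambda_max <- max(e$values)
  mu <- (2 / lambda_max) * e$values - 1
  tkm2 <- rep(1, length(mu)); g <- theta[1L] * tkm2
  if (length(theta) >= 2L) {
    tkm1 <- mu
    g <- g + theta[2L] * tkm1
    k <- 3L
    while (k <= length(theta)) {
      tk <- 2 * mu * tkm1 - tkm2
      g <- g + theta[k] * tk
      tkm2 <- tkm1; tkm1 <- tk
      k <- k + 1L
    }
  }
  e$vectors %*% (g * (t(e$vectors) %*% X))
}

#' Global add pooling
#'
#' Node-permutation-invariant readout: column sums of the node-feature
#' matrix.
#'
#' @param H n x f matrix.
#' @return Length-f vector.
#' @export
global_add_pool <- function(H) colSums(as.matrix(H))

#' Reshape a 64-vector to an 8 x 8 x 1 grid
#'
#' Row-major filling; `reshape_grid` and its inverse round-trip exactly.
#'
#' @param v Numeric vector of length 64.
#' @return 8 x 8 x 1 array.
#' @export
reshape_grid <- function(v) {
  if (length(v) != 64L) stop("need a 64-vector, got length ", length(v))
  array(matrix(v, 8L, 8L, byrow = TRUE), c(8L, 8L, 1L))
}

#' Inverse of [reshape_grid()]
#' @param g 8 x 8 x 1 array.
#' @return Length-64 vector (row-major read-out).
#' @export
unreshape_grid <- function(g) as.vector(t(g[, , 1L]))

# ---- SRM (style-based recalibration) -------------------------------------

.srm_style <- function(U, eps) {
  # U: (N, H, W, C) -> list(mu, sigma) each (N, C), population std with eps
  d <- dim(U)
  m <- matrix(aperm(U, c(2L, 3L, 1L, 4L)), d[2L] * d[3L], d[1L] * d[4L])
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  list(mu = matrix(mu, d[1L], d[4L]),
       sigma = matrix(sqrt(pmax(v, 0) + eps), d[1L], d[4L]),
       v = matrix(pmax(v, 0), d[1L], d[4L]))
}

.srm_forward <- function(U, par, state, mode, bn_eps = 1e-5, style_eps = 1e-5,
                         momentum = 0.1) {
  # par: cfc_w (C x 2), cfc_b, bn_gamma, bn_beta; state: run_mean, run_var
  d <- dim(U); N <- d[1L]; C <- d[4L]
  st <- .srm_style(U, style_eps)
  z <- sweep(st$mu, 2L, par$cfc_w[, 1L], `*`) +
       sweep(st$sigma, 2L, par$cfc_w[, 2L], `*`)
  z <- sweep(z, 2L, par$cfc_b, `+`)
  if (mode == "train") {
    bm <- colMeans(z)
    bv <- colMeans(sweep(z, 2L, bm)^2)
    state$run_mean <- if (anyNA(state$run_mean)) bm else
      (1 - momentum) * state$run_mean + momentum * bm
    state$run_var <- if (anyNA(state$run_var)) bv else
      (1 - momentum) * state$run_var + momentum * bv
  } else {
    if (anyNA(state$run_mean)) stop("SRM eval mode with uninitialized running statistics")
    bm <- state$run_mean; bv <- state$run_var
  }
  zc <- sweep(z, 2L, bm)
  inv <- 1 / sqrt(bv + bn_eps)
  zhat <- sweep(zc, 2L, inv, `*`)
  zt <- sweep(sweep(zhat, 2L, par$bn_gamma, `*`), 2L, par$bn_beta, `+`)
  g <- .sigmoid(zt)
  # broadcast g (N, C) over (N, H, W, C)
  gfull <- aperm(array(g, c(N, C, d[2L], d[3L])), c(1L, 3L, 4L, 2L))
  list(out = U * gfull, g = g, gfull = gfull, zt = zt, zhat = zhat,
       inv = inv, zc = zc, z = z, style = st, state = state,
       batch_mean = bm, batch_var = bv)
}

#' Style-based recalibration of a feature map
#'
#' Channel attention: per sample and channel, the spatial mean and standard
#' deviation ("style features") pass through a per-channel linear map, batch
#' normalization over the mini-batch, and a sigmoid; the resulting gate in
#' (0, 1) rescales the channel.
#'
#' @param U N x C x H x W array (batch, channels, spatial dims).
#' @param cfc_w C x 2 matrix of per-channel weights on (mean, sd).
#' @param cfc_b,bn_gamma,bn_beta Length-C vectors.
#' @param run_mean,run_var Running statistics for eval mode (length C).
#' @param mode `"train"` (batch statistics) or `"eval"` (running statistics).
#' @return N x C x H x W recalibrated array, with attribute `"gates"`
#'   holding the N x C gate matrix.
#' @export
srm <- function(U, cfc_w, cfc_b = 0, bn_gamma = 1, bn_beta = 0,
                run_mean = NULL, run_var = NULL, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  d <- dim(U)
  stopifnot(length(d) == 4L)
  C <- d[2L]
  par <- list(cfc_w = matrix(cfc_w, C, 2L), cfc_b = rep(cfc_b, length.out = C),
              bn_gamma = rep(bn_gamma, length.out = C),
              bn_beta = rep(bn_beta, length.out = C))
  state <- list(run_mean = run_mean %||% rep(NA_real_, C),
                run_var = run_var %||% rep(NA_real_, C))
  Ui <- aperm(U, c(1L, 3L, 4L, 2L))             # -> (N, H, W, C)
  f <- .srm_forward(Ui, par, state, mode)
  out <- aperm(f$out, c(1L, 4L, 2L, 3L))        # -> (N, C, H, W)
  attr(out, "gates") <- f$g
  out
}

# ---- convolution helpers --------------------------------------------------

.im2col <- function(Xin, kh = 2L, kw = 2L) {
  d <- dim(Xin)  # (N, H, W, Cin)
  oh <- d[2L] - kh + 1L; ow <- d[3L] - kw + 1L
  P <- matrix(0, d[1L] * oh * ow, kh * kw * d[4L])
  col <- 0L
  for (cin in seq_len(d[4L])) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    col <- di + kh * (dj - 1L) + kh * kw * (cin - 1L)
    P[, col] <- as.vector(Xin[, di:(di + oh - 1L), dj:(dj + ow - 1L), cin])
  }
  P
}

.col2im <- function(dP, dims, kh = 2L, kw = 2L) {
  oh <- dims[2L] - kh + 1L; ow <- dims[3L] - kw + 1L
  dX <- array(0, dims)
  for (cin in seq_len(dims[4L])) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    col <- di + kh * (dj - 1L) + kh * kw * (cin - 1L)
    dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), cin] <-
      dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), cin] +
      array(dP[, col], c(dims[1L], oh, ow))
  }
  dX
}

.conv2d <- function(Xin, K, b) {
  # valid 2x2 convolution, stride 1; K: (kh, kw, Cin, Cout)
  d <- dim(Xin); kd <- dim(K)
  P <- .im2col(Xin, kd[1L], kd[2L])
  out <- P %*% matrix(K, kd[1L] * kd[2L] * kd[3L], kd[4L])
  out <- sweep(out, 2L, b, `+`)
  array(out, c(d[1L], d[2L] - kd[1L] + 1L, d[3L] - kd[2L] + 1L, kd[4L]))
}

.maxpool2 <- function(Xin) {
  # 2x2 window, stride 2; input (N, H, W, C) with even H, W
  d <- dim(Xin)
  i1 <- seq(1L, d[2L], 2L); j1 <- seq(1L, d[3L], 2L)
  s11 <- Xin[, i1, j1, , drop = FALSE]
  s21 <- Xin[, i1 + 1L, j1, , drop = FALSE]
  s12 <- Xin[, i1, j1 + 1L, , drop = FALSE]
  s22 <- Xin[, i1 + 1L, j1 + 1L, , drop = FALSE]
  out <- pmax(s11, s21, s12, s22)
  m11 <- s11 == out
  m21 <- (s21 == out) & !m11
  m12 <- (s12 == out) & !m11 & !m21
  m22 <- (s22 == out) & !m11 & !m21 & !m12
  list(out = out, masks = list(m11, m21, m12, m22))
}

.maxpool2_back <- function(dOut, masks, dims) {
  d <- dims
  i1 <- seq(1L, d[2L], 2L); j1 <- seq(1L, d[3L], 2L)
  dX <- array(0, d)
  dX[, i1, j1, ] <- dOut * masks[[1L]]
  dX[, i1 + 1L, j1, ] <- dOut * masks[[2L]]
  dX[, i1, j1 + 1L, ] <- dOut * masks[[3L]]
  dX[, i1 + 1L, j1 + 1L, ] <- dOut * masks[[4L]]
  dX
}

# ---- parameter initialization --------------------------------------------

.glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Initialize all model parameters
#'
#' Glorot-uniform weights for the GCN, convolutional and fully connected
#' layers; zero biases; SRM channel weights Glorot, batch-norm scale 1 and
#' shift 0; the learnable adjacency starts at the supplied initializer.
#'
#' @param n Number of graph nodes (channels).
#' @param f Node feature dimension (bands).
#' @param n_classes Number of output classes.
#' @param adjacency Initial adjacency: an [adjacency_matrix()] or n x n
#'   matrix.
#' @param gcn_dims Output widths of the GCN layers; the last must be 64 so
#'   the pooled vector tiles the 8 x 8 grid. Default `c(16, 64)`; a single
#'   value `64` gives the one-layer variant.
#' @param use_srm Logical; `FALSE` replaces SRM gates with identity (the
#'   ablation switch).
#' @param leaky_slope Leaky-ReLU negative slope.
#' @param dropout Dropout rate applied after FC1 and FC2 in training.
#' @param seed RNG seed for initialization.
#' @return Object of class `"dgcn_params"`: list with `tensors` (trainable
#'   arrays), `state` (SRM running statistics), `config`.
#' @export
model_init <- function(n, f, n_classes, adjacency, gcn_dims = c(16L, 64L),
                       use_srm = TRUE, leaky_slope = 0.01, dropout = 0.7,
                       seed = 1L) {
  stopifnot(length(gcn_dims) >= 1L, length(gcn_dims) <= 3L,
            gcn_dims[length(gcn_dims)] == 64L)
  A0 <- if (inherits(adjacency, "eeg_adjacency")) adjacency$weights else as.matrix(adjacency)
  stopifnot(nrow(A0) == n, ncol(A0) == n)
  set.seed(seed)
  tensors <- list(A = A0)
  dims_in <- c(f, gcn_dims[-length(gcn_dims)])
  for (l in seq_along(gcn_dims)) {
    tensors[[paste0("gcn_W", l)]] <- .glorot(dims_in[l], gcn_dims[l])
  }
  tensors$conv1_K <- .glorot(4L, 16L, c(2L, 2L, 1L, 16L))
  tensors$conv1_b <- numeric(16L)
  tensors$srm1_w <- .glorot(2L, 1L, c(16L, 2L))
  tensors$srm1_b <- numeric(16L)
  tensors$srm1_gamma <- rep(1, 16L)
  tensors$srm1_beta <- numeric(16L)
  tensors$conv2_K <- .glorot(4L * 16L, 32L, c(2L, 2L, 16L, 32L))
  tensors$conv2_b <- numeric(32L)
  tensors$srm2_w <- .glorot(2L, 1L, c(32L, 2L))
  tensors$srm2_b <- numeric(32L)
  tensors$srm2_gamma <- rep(1, 32L)
  tensors$srm2_beta <- numeric(32L)
  fuse <- sum(gcn_dims) + 3L * 3L * 32L
  tensors$fc1_W <- .glorot(fuse, 256L); tensors$fc1_b <- numeric(256L)
  tensors$fc2_W <- .glorot(256L, 128L); tensors$fc2_b <- numeric(128L)
  tensors$fc3_W <- .glorot(128L, n_classes); tensors$fc3_b <- numeric(n_classes)
  structure(
    list(tensors = tensors,
         state = list(srm1_mean = rep(NA_real_, 16L), srm1_var = rep(NA_real_, 16L),
                      srm2_mean = rep(NA_real_, 32L), srm2_var = rep(NA_real_, 32L)),
         config = list(n = as.integer(n), f = as.integer(f),
                       n_classes = as.integer(n_classes),
                       gcn_dims = as.integer(gcn_dims), use_srm = use_srm,
                       leaky_slope = leaky_slope, dropout = dropout,
                       fuse_width = as.integer(fuse),
                       bn_eps = 1e-5, style_eps = 1e-5, bn_momentum = 0.1)),
    class = "dgcn_params")
}

# ---- full forward pass ----------------------------------------------------

.identity_srm <- function(U) {
  d <- dim(U)
  list(out = U, g = matrix(1, d[1L], d[4L]), identity = TRUE)
}

.forward_full <- function(params, X, mode = c("eval", "train"),
                          drop_masks = NULL) {
  # X: (N, n, f) array; returns probabilities plus every intermediate needed
  # for backpropagation.
  mode <- match.arg(mode)
  cfg <- params$config; tn <- params$tensors
  d <- dim(X); N <- d[1L]
  stopifnot(d[2L] == cfg$n, d[3L] == cfg$f)
  slope <- cfg$leaky_slope
  P <- gcn_propagation(tn$A, renormalize = TRUE)
  L <- length(cfg$gcn_dims)
  Zs <- Hs <- vector("list", L)
  pooled <- vector("list", L)
  Hprev <- X
  for (l in seq_len(L)) {
    W <- tn[[paste0("gcn_W", l)]]
    Zl <- array(0, c(N, cfg$n, ncol(W)))
    for (i in seq_len(N)) {
      Zl[i, , ] <- P %*% Hprev[i, , ] %*% W
    }
    Hl <- .lrelu(Zl, slope)
    Zs[[l]] <- Zl; Hs[[l]] <- Hl
    pooled[[l]] <- apply(Hl, c(1L, 3L), sum)   # (N, width): add pool per sample
    Hprev <- Hl
  }
  p_last <- pooled[[L]]                         # (N, 64)
  # row-major reshape to (N, 8, 8, 1)
  grid <- array(0, c(N, 8L, 8L, 1L))
  for (i in seq_len(N)) grid[i, , , 1L] <- matrix(p_last[i, ], 8L, 8L, byrow = TRUE)
  # conv1 -> lrelu -> SRM1
  C1z <- .conv2d(grid, tn$conv1_K, tn$conv1_b)           # (N,7,7,16)
  C1a <- .lrelu(C1z, slope)
  srm1 <- if (cfg$use_srm) {
    .srm_forward(C1a, list(cfc_w = tn$srm1_w, cfc_b = tn$srm1_b,
                           bn_gamma = tn$srm1_gamma, bn_beta = tn$srm1_beta),
                 list(run_mean = params$state$srm1_mean,
                      run_var = params$state$srm1_var),
                 mode, cfg$bn_eps, cfg$style_eps, cfg$bn_momentum)
  } else .identity_srm(C1a)
  R1 <- srm1$out
  # conv2 -> lrelu -> SRM2
  C2z <- .conv2d(R1, tn$conv2_K, tn$conv2_b)             # (N,6,6,32)
  C2a <- .lrelu(C2z, slope)
  srm2 <- if (cfg$use_srm) {
    .srm_forward(C2a, list(cfc_w = tn$srm2_w, cfc_b = tn$srm2_b,
                           bn_gamma = tn$srm2_gamma, bn_beta = tn$srm2_beta),
                 list(run_mean = params$state$srm2_mean,
                      run_var = params$state$srm2_var),
                 mode, cfg$bn_eps, cfg$style_eps, cfg$bn_momentum)
  } else .identity_srm(C2a)
  R2 <- srm2$out
  mp <- .maxpool2(R2)                                    # (N,3,3,32)
  flat <- matrix(mp$out, N, 3L * 3L * 32L)               # column-major flatten
  Fmat <- cbind(do.call(cbind, pooled[-L]), p_last, flat)
  if (L == 1L) Fmat <- cbind(p_last, flat)
  stopifnot(ncol(Fmat) == cfg$fuse_width)
  # classifier
  z1 <- sweep(Fmat %*% tn$fc1_W, 2L, tn$fc1_b, `+`)
  h1 <- .lrelu(z1, slope)
  if (mode == "train") {
    if (is.null(drop_masks)) {
      keep <- 1 - cfg$dropout
      drop_masks <- list(
        m1 = matrix(stats::rbinom(length(h1), 1L, keep) / keep, nrow = N),
        m2 = matrix(stats::rbinom(N * 128L, 1L, keep) / keep, nrow = N))
    }
    h1d <- h1 * drop_masks$m1
  } else h1d <- h1
  z2 <- sweep(h1d %*% tn$fc2_W, 2L, tn$fc2_b, `+`)
  h2 <- .lrelu(z2, slope)
  h2d <- if (mode == "train") h2 * drop_masks$m2 else h2
  logits <- sweep(h2d %*% tn$fc3_W, 2L, tn$fc3_b, `+`)
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  if (anyNA(probs)) stop("NaN in forward pass at softmax")
  list(probs = probs, logits = logits, Fmat = Fmat, pooled = pooled,
       X = X, P = P, Zs = Zs, Hs = Hs, grid = grid,
       C1z = C1z, C1a = C1a, srm1 = srm1, R1 = R1,
       C2z = C2z, C2a = C2a, srm2 = srm2, R2 = R2, mp = mp, flat = flat,
       z1 = z1, h1 = h1, h1d = h1d, z2 = z2, h2 = h2, h2d = h2d,
       drop_masks = if (mode == "train") drop_masks else NULL,
       new_state = if (cfg$use_srm) list(srm1_mean = srm1$state$run_mean,
                                         srm1_var = srm1$state$run_var,
                                         srm2_mean = srm2$state$run_mean,
                                         srm2_var = srm2$state$run_var)
                   else params$state)
}

#' Style-recalibrated convolutional stack
#'
#' `(8, 8, 1)` grid -> 2x2 conv (16 maps) -> leaky-ReLU -> SRM -> 2x2 conv
#' (32 maps) -> leaky-ReLU -> SRM -> 2x2/stride-2 max pool -> `(3, 3, 32)`.
#'
#' @param grid An 8 x 8 x 1 array (one sample) or N x 8 x 8 x 1 batch.
#' @param params A [model_init()] object supplying the conv/SRM parameters.
#' @param mode `"train"` or `"eval"` (affects SRM batch statistics; eval
#'   requires initialized running statistics).
#' @return 3 x 3 x 32 array (or N x 3 x 3 x 32 for a batch input).
#' @export
conv_stack <- function(grid, params, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  single <- length(dim(grid)) == 3L
  if (single) grid <- array(grid, c(1L, dim(grid)))
  cfg <- params$config; tn <- params$tensors
  C1a <- .lrelu(.conv2d(grid, tn$conv1_K, tn$conv1_b), cfg$leaky_slope)
  s1 <- if (cfg$use_srm) {
    .srm_forward(C1a, list(cfc_w = tn$srm1_w, cfc_b = tn$srm1_b,
                           bn_gamma = tn$srm1_gamma, bn_beta = tn$srm1_beta),
                 list(run_mean = params$state$srm1_mean,
                      run_var = params$state$srm1_var),
                 mode, cfg$bn_eps, cfg$style_eps, cfg$bn_momentum)
  } else .identity_srm(C1a)
  C2a <- .lrelu(.conv2d(s1$out, tn$conv2_K, tn$conv2_b), cfg$leaky_slope)
  s2 <- if (cfg$use_srm) {
    .srm_forward(C2a, list(cfc_w = tn$srm2_w, cfc_b = tn$srm2_b,
                           bn_gamma = tn$srm2_gamma, bn_beta = tn$srm2_beta),
                 list(run_mean = params$state$srm2_mean,
                      run_var = params$state$srm2_var),
                 mode, cfg$bn_eps, cfg$style_eps, cfg$bn_momentum)
  } else .identity_srm(C2a)
  out <- .maxpool2(s2$out)$out
  if (single) array(out, dim(out)[-1L]) else out
}

#' Full forward pass of the model
#'
#' Computes class probabilities and the fused multi-level feature vector for
#' a batch of segments.
#'
#' @param features n x f matrix (one segment) or N x n x f array (batch).
#' @param params A [model_init()] object (or the `params` of a fitted
#'   model).
#' @param mode `"eval"` (deterministic; default) or `"train"` (dropout and
#'   SRM batch statistics active).
#' @return List with `probs` (N x C), `fused` (N x fuse_width) and `pooled`
#'   (per-GCN-layer pooled features).
#' @export
model_forward <- function(features, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (length(dim(features)) == 2L) {
    features <- array(features, c(1L, dim(features)))
  }
  fw <- .forward_full(params, features, mode)
  list(probs = fw$probs, fused = fw$Fmat, pooled = fw$pooled)
}
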