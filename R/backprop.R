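# Analytic gradients of the regularized cross-entropy loss with respect to
# every trainable tensor, including the adjacency matrix (through
# rectification, symmetrization, self-loops and degree renormalization).
# Verified against central finite differences in the test suite.

#' Regularized cross-entropy loss
#'
#' Mean cross-entropy of predicted class probabilities plus an L2 penalty
#' `alpha * ||Theta||^2` over the supplied parameter tensors (or the
#' unsquared norm `alpha * ||Theta||` when `squared = FALSE`).
#'
#' @param probs N x C matrix of predicted probabilities (rows sum to 1).
#' @param labels Integer vector of 0-based true classes.
#' @param tensors Optional named list of parameter arrays entering the
#'   penalty.
#' @param alpha Regularization coefficient (default 0).
#' @param squared Use the squared norm (default `TRUE`).
#' @return Nonnegative scalar loss.
#' @export
loss_cross_entropy <- function(probs, labels, tensors = NULL, alpha = 0,
                               squared = TRUE) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= ncol(probs))) {
    stop("label out of range [0, C)")
  }
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  ce <- -mean(log(pmax(p, 1e-12)))
  reg <- 0
  if (alpha > 0 && length(tensors)) {
    ssq <- sum(vapply(tensors, function(t) sum(t^2), 0))
    reg <- if (squared) alpha * ssq else alpha * sqrt(ssq)
  }
  ce + reg
}

.bcast_nc <- function(x, dims) {
  # (N, C) -> (N, H, W, C)
  aperm(array(x, c(dims[1L], dims[4L], dims[2L], dims[3L])), c(1L, 3L, 4L, 2L))
}

.srm_backward <- function(dOut, f, U, par) {
  # f: output of .srm_forward on U; returns dU and parameter gradients
  d <- dim(U); N <- d[1L]; HW <- d[2L] * d[3L]; C <- d[4L]
  dU <- dOut * f$gfull
  prod_ <- dOut * U
  m <- matrix(aperm(prod_, c(2L, 3L, 1L, 4L)), HW, N * C)
  dg <- matrix(colSums(m), N, C)
  dzt <- dg * f$g * (1 - f$g)
  dgamma <- colSums(dzt * f$zhat)
  dbeta <- colSums(dzt)
  dzhat <- sweep(dzt, 2L, par$bn_gamma, `*`)
  s1 <- colSums(dzhat)
  s2 <- colSums(dzhat * f$zhat)
  dz <- sweep(N * dzhat -
                matrix(s1, N, C, byrow = TRUE) -
                f$zhat * matrix(s2, N, C, byrow = TRUE),
              2L, f$inv / N, `*`)
  dw1 <- colSums(dz * f$style$mu)
  dw2 <- colSums(dz * f$style$sigma)
  db <- colSums(dz)
  dmu <- sweep(dz, 2L, par$cfc_w[, 1L], `*`)
  dsig <- sweep(dz, 2L, par$cfc_w[, 2L], `*`)
  dv <- dsig * 0.5 / f$style$sigma
  mub <- .bcast_nc(f$style$mu, d)
  dU <- dU + .bcast_nc(dmu, d) / HW +
    (2 / HW) * (U - mub) * .bcast_nc(dv, d)
  list(dU = dU,
       cfc_w = cbind(dw1, dw2), cfc_b = db,
       bn_gamma = dgamma, bn_beta = dbeta)
}

.conv_backward <- function(dOut, Xin, K) {
  # dOut: (N, oh, ow, Cout); returns dX, dK, db
  kd <- dim(K); d <- dim(Xin)
  Pm <- .im2col(Xin, kd[1L], kd[2L])
  dOm <- matrix(dOut, prod(dim(dOut)[1:3]), kd[4L])
  Kmat <- matrix(K, kd[1L] * kd[2L] * kd[3L], kd[4L])
  dK <- array(crossprod(Pm, dOm), kd)
  db <- colSums(dOm)
  dX <- .col2im(dOm %*% t(Kmat), d, kd[1L], kd[2L])
  list(dX = dX, dK = dK, db = db)
}

.propagation_backward <- function(dP, A) {
  # gradient of L wrt raw A through: symmetrize, abs, +I, degree-normalize
  As <- (A + t(A)) / 2
  Aabs <- abs(As)
  n <- nrow(A)
  B <- Aabs + diag(n)
  deg <- rowSums(B)
  dis <- 1 / sqrt(deg)
  dB <- dP * outer(dis, dis)
  GB <- dP * B
  r <- as.vector(GB %*% dis + t(GB) %*% dis)
  dd <- r * (-0.5) * deg^(-1.5)
  dB <- dB + matrix(dd, n, n)
  dAs <- dB * sign(As)
  (dAs + t(dAs)) / 2
}

.backward_full <- function(params, fw, labels) {
  cfg <- params$config; tn <- params$tensors
  N <- nrow(fw$probs); C <- ncol(fw$probs)
  slope <- cfg$leaky_slope
  L <- length(cfg$gcn_dims)
  grads <- list()
  Y <- matrix(0, N, C); Y[cbind(seq_len(N), labels + 1L)] <- 1
  dlogits <- (fw$probs - Y) / N
  grads$fc3_W <- crossprod(fw$h2d, dlogits)
  grads$fc3_b <- colSums(dlogits)
  dh2d <- dlogits %*% t(tn$fc3_W)
  dh2 <- if (!is.null(fw$drop_masks)) dh2d * fw$drop_masks$m2 else dh2d
  dz2 <- dh2 * .lrelu_grad(fw$z2, slope)
  grads$fc2_W <- crossprod(fw$h1d, dz2)
  grads$fc2_b <- colSums(dz2)
  dh1d <- dz2 %*% t(tn$fc2_W)
  dh1 <- if (!is.null(fw$drop_masks)) dh1d * fw$drop_masks$m1 else dh1d
  dz1 <- dh1 * .lrelu_grad(fw$z1, slope)
  grads$fc1_W <- crossprod(fw$Fmat, dz1)
  grads$fc1_b <- colSums(dz1)
  dF <- dz1 %*% t(tn$fc1_W)
  # split the fused vector
  widths <- c(cfg$gcn_dims, 288L)
  dpooled <- vector("list", L)
  off <- 0L
  for (l in seq_len(L)) {
    dpooled[[l]] <- dF[, (off + 1L):(off + widths[l]), drop = FALSE]
    off <- off + widths[l]
  }
  dflat <- dF[, (off + 1L):(off + 288L), drop = FALSE]
  # conv branch
  dmp <- array(dflat, c(N, 3L, 3L, 32L))
  dR2 <- .maxpool2_back(dmp, fw$mp$masks, dim(fw$R2))
  if (cfg$use_srm) {
    sb2 <- .srm_backward(dR2, fw$srm2, fw$C2a,
                         list(cfc_w = tn$srm2_w, bn_gamma = tn$srm2_gamma))
    dC2a <- sb2$dU
    grads$srm2_w <- sb2$cfc_w; grads$srm2_b <- sb2$cfc_b
    grads$srm2_gamma <- sb2$bn_gamma; grads$srm2_beta <- sb2$bn_beta
  } else dC2a <- dR2
  dC2z <- dC2a * .lrelu_grad(fw$C2z, slope)
  cb2 <- .conv_backward(dC2z, fw$R1, tn$conv2_K)
  grads$conv2_K <- cb2$dK; grads$conv2_b <- cb2$db
  dR1 <- cb2$dX
  if (cfg$use_srm) {
    sb1 <- .srm_backward(dR1, fw$srm1, fw$C1a,
                         list(cfc_w = tn$srm1_w, bn_gamma = tn$srm1_gamma))
    dC1a <- sb1$dU
    grads$srm1_w <- sb1$cfc_w; grads$srm1_b <- sb1$cfc_b
    grads$srm1_gamma <- sb1$bn_gamma; grads$srm1_beta <- sb1$bn_beta
  } else dC1a <- dR1
  dC1z <- dC1a * .lrelu_grad(fw$C1z, slope)
  cb1 <- .conv_backward(dC1z, fw$grid, tn$conv1_K)
  grads$conv1_K <- cb1$dK; grads$conv1_b <- cb1$db
  dgrid <- cb1$dX
  # grid gradient flows back into the last pooled vector (row-major)
  dp_grid <- t(vapply(seq_len(N),
                      function(i) as.vector(t(dgrid[i, , , 1L])), numeric(64L)))
  dpooled[[L]] <- dpooled[[L]] + dp_grid
  # GCN branch
  dP <- matrix(0, cfg$n, cfg$n)
  dH <- NULL
  for (l in L:1L) {
    Wl <- tn[[paste0("gcn_W", l)]]
    Hprev <- if (l == 1L) fw$X else fw$Hs[[l - 1L]]
    dHl <- array(0, dim(fw$Hs[[l]]))
    for (j in seq_len(dim(dHl)[3L])) dHl[, , j] <- dpooled[[l]][, j]
    if (!is.null(dH)) dHl <- dHl + dH
    dZ <- dHl * .lrelu_grad(fw$Zs[[l]], slope)
    dWl <- matrix(0, nrow(Wl), ncol(Wl))
    dHprev <- array(0, dim(Hprev))
    for (i in seq_len(N)) {
      Hp <- Hprev[i, , ]
      dZi <- dZ[i, , ]
      PH <- fw$P %*% Hp
      dWl <- dWl + crossprod(PH, dZi)
      dP <- dP + dZi %*% t(Hp %*% Wl)
      dHprev[i, , ] <- t(fw$P) %*% dZi %*% t(Wl)
    }
    grads[[paste0("gcn_W", l)]] <- dWl
    dH <- dHprev
  }
  grads$A <- .propagation_backward(dP, tn$A)
  grads
}

.add_l2_grads <- function(grads, tensors, alpha, squared, include_A) {
  if (alpha <= 0) return(grads)
  names_pen <- names(tensors)
  if (!include_A) names_pen <- setdiff(names_pen, "A")
  if (squared) {
    for (nm in names_pen) grads[[nm]] <- grads[[nm]] + 2 * alpha * tensors[[nm]]
  } else {
    nrm <- sqrt(sum(vapply(tensors[names_pen], function(t) sum(t^2), 0)))
    if (nrm > 0) {
      for (nm in names_pen) grads[[nm]] <- grads[[nm]] + alpha * tensors[[nm]] / nrm
    }
  }
  grads
}

#' Loss and analytic gradients for one batch
#'
#' Runs the forward pass in training mode (optionally with fixed dropout
#' masks) and returns the regularized loss together with the gradient of
#' the loss with respect to every trainable tensor, including the
#' adjacency. Exposed mainly so the gradients can be checked against finite
#' differences.
#'
#' @param params A [model_init()] object.
#' @param features N x n x f array.
#' @param labels 0-based integer labels.
#' @param alpha L2 coefficient.
#' @param squared Squared-norm penalty (default `TRUE`).
#' @param include_adjacency Penalize `A` too (default `TRUE`).
#' @param drop_masks Optional fixed dropout masks (list `m1`, `m2`).
#' @return List with `loss`, `grads` (named like `params$tensors`), `probs`.
#' @export
model_loss_grad <- function(params, features, labels, alpha = 0,
                            squared = TRUE, include_adjacency = TRUE,
                            drop_masks = NULL) {
  if (length(dim(features)) == 2L) features <- array(features, c(1L, dim(features)))
  fw <- .forward_full(params, features, "train", drop_masks = drop_masks)
  pen <- params$tensors
  if (!include_adjacency) pen$A <- NULL
  loss <- loss_cross_entropy(fw$probs, labels, pen, alpha, squared)
  grads <- .backward_full(params, fw, labels)
  grads <- .add_l2_grads(grads, params$tensors, alpha, squared, include_adjacency)
  list(loss = loss, grads = grads, probs = fw$probs, forward = fw)
}
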