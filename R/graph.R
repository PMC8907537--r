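# Channel-connectivity graphs: |PCC| and PLV initializers, random graphs,
# and the symmetric degree-normalized propagation operator used by the GCN.

#' Construct an adjacency-matrix object
#'
#' @param weights n x n nonnegative symmetric numeric matrix.
#' @param channel_names Channel labels (length n).
#' @param initializer One of `"pcc"`, `"plv"`, `"random"`, `"external"`.
#' @param is_learned Logical: does this matrix come out of training?
#' @return Object of class `"eeg_adjacency"`.
#' @export
adjacency_matrix <- function(weights, channel_names = NULL,
                             initializer = "external", is_learned = FALSE) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n, all(is.finite(weights)), all(weights >= 0))
  if (max(abs(weights - t(weights))) > 1e-8) stop("adjacency must be symmetric")
  if (is.null(channel_names)) channel_names <- seed_channels(n)
  stopifnot(length(channel_names) == n)
  dimnames(weights) <- list(channel_names, channel_names)
  structure(list(weights = weights, channel_names = channel_names,
                 initializer = initializer, is_learned = is_learned),
            class = "eeg_adjacency")
}

#' @export
print.eeg_adjacency <- function(x, ...) {
  cat(sprintf("<eeg_adjacency> %d channels, initializer = %s%s\n",
              nrow(x$weights), x$initializer,
              if (x$is_learned) " (learned)" else ""))
  invisible(x)
}

#' @export
as.matrix.eeg_adjacency <- function(x, ...) x$weights

.signal_matrix <- function(x) {
  # channels x observations matrix from a raw matrix, recording or featureset
  if (inherits(x, "eeg_recording")) {
    list(m = x$signal, names = x$channel_names)
  } else if (inherits(x, "eeg_featureset")) {
    # vectorize band features across segments: one row per channel
    d <- dim(x$features)
    m <- matrix(aperm(x$features, c(2L, 1L, 3L)), nrow = d[2])
    list(m = m, names = x$channel_names)
  } else {
    m <- as.matrix(x)
    list(m = m, names = rownames(m) %||% seed_channels(nrow(m)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Absolute-Pearson-correlation adjacency
#'
#' Edge weight `A[i, j] = |cov(x_i, x_j) / (sigma_i sigma_j)|`, the absolute
#' Pearson correlation between channels; the diagonal is 1. Accepts a raw
#' channels x samples matrix, an [eeg_recording()] (channels over time) or
#' an [eeg_featureset()] (each channel's band features vectorized across
#' segments).
#'
#' @param x Signal source (see above).
#' @return An [adjacency_matrix()] with `initializer = "pcc"`.
#' @export
#' @examples
#' pcc_adjacency(matrix(rnorm(40), nrow = 4))
pcc_adjacency <- function(x) {
  s <- .signal_matrix(x)
  if (ncol(s$m) < 2L) stop("need at least 2 samples per channel")
  sds <- apply(s$m, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant channel(s): %s",
                 paste(s$names[sds == 0], collapse = ", ")))
  }
  w <- abs(stats::cor(t(s$m)))
  diag(w) <- 1
  adjacency_matrix(w, s$names, initializer = "pcc")
}

.analytic_signal <- function(v) {
  # analytic signal via the frequency-domain Hilbert construction
  n <- length(v)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(v) * h, inverse = TRUE) / n
}

#' Phase-locking-value adjacency
#'
#' `A[i, j]` is the magnitude of the mean phase-difference phasor
#' `|mean_t exp(i (phi_i(t) - phi_j(t)))|`, with `phi` the instantaneous
#' phase of the analytic signal. By default the signal is band-passed to the
#' alpha band (8-12 Hz) first when a sampling rate is available; pass
#' `band = NULL` to use the broadband signal.
#'
#' @param x channels x samples matrix or [eeg_recording()].
#' @param sampling_rate Hz; taken from the recording when `x` is one.
#' @param band Length-2 numeric `(low, high)` in Hz, or `NULL` for broadband.
#' @return An [adjacency_matrix()] with `initializer = "plv"`.
#' @export
plv_adjacency <- function(x, sampling_rate = NULL, band = c(8, 12)) {
  s <- .signal_matrix(x)
  if (inherits(x, "eeg_recording") && is.null(sampling_rate)) {
    sampling_rate <- x$sampling_rate
  }
  if (ncol(s$m) < 16L) stop("need at least 16 samples for PLV")
  sds <- apply(s$m, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant channel(s): %s",
                 paste(s$names[sds == 0], collapse = ", ")))
  }
  m <- s$m
  if (!is.null(band) && !is.null(sampling_rate)) {
    m <- bandpass_filter(m, band[1], band[2], sampling_rate)
  }
  phases <- t(apply(m, 1L, function(v) Arg(.analytic_signal(v))))
  n <- nrow(m)
  w <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w[i, j] <- w[j, i] <- Mod(mean(exp(1i * (phases[i, ] - phases[j, ]))))
  }
  adjacency_matrix(w, s$names, initializer = "plv")
}

#' Random adjacency initializer
#'
#' I.i.d. Uniform(0, 1) weights on the upper triangle, symmetrized, with a
#' unit diagonal; reproducible for a given seed.
#'
#' @param n Number of channels.
#' @param seed Integer RNG seed.
#' @param channel_names Optional labels.
#' @return An [adjacency_matrix()] with `initializer = "random"`.
#' @export
random_adjacency <- function(n, seed = 1L, channel_names = NULL) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1L) / 2L)
  w <- w + t(w)
  diag(w) <- 1
  adjacency_matrix(w, channel_names %||% seed_channels(n), initializer = "random")
}

#' Symmetric degree-normalized propagation operator
#'
#' The operator the graph-convolution layer multiplies by. With
#' `renormalize = TRUE` (the form the model uses) self-loops are added and
#' the result is `D~^-1/2 (A + I) D~^-1/2`; with `renormalize = FALSE` the
#' pre-renormalization first-order spectral filter `I + D^-1/2 A D^-1/2` is
#' returned, which coincides exactly with the order-1 Chebyshev filter at
#' `lambda_max = 2`, `theta_0 = -theta_1 = 1` (see [chebyshev_filter()]).
#' Negative entries of `A` are rectified with the absolute value and the
#' matrix is symmetrized first, so the operator is defined for a learned,
#' unconstrained adjacency.
#'
#' @param A Square matrix or [adjacency_matrix()].
#' @param renormalize Add self-loops and renormalize (default `TRUE`).
#' @return n x n symmetric operator with spectral radius at most 1
#'   (`renormalize = TRUE`) or at most 2.
#' @export
gcn_propagation <- function(A, renormalize = TRUE) {
  A <- if (inherits(A, "eeg_adjacency")) A$weights else as.matrix(A)
  A <- abs((A + t(A)) / 2)
  n <- nrow(A)
  if (renormalize) {
    At <- A + diag(n)
    d <- rowSums(At)
    stopifnot(all(d > 0))  # guaranteed by self-loops
    dis <- 1 / sqrt(d)
    At * outer(dis, dis)
  } else {
    d <- rowSums(A)
    if (any(d <= 0)) stop("isolated node: zero degree without self-loops")
    dis <- 1 / sqrt(d)
    diag(n) + A * outer(dis, dis)
  }
}
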