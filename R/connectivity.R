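# Post-hoc interpretation of the learned adjacency: min-max normalization,
# top-k edge ranking on named channels, local/global labeling, and per-edge
# change between the initial and learned graphs.

.adj_weights <- function(A) {
  if (inherits(A, "eeg_adjacency")) A$weights
  else if (inherits(A, "dgcn")) abs((A$params$tensors$A + t(A$params$tensors$A)) / 2)
  else as.matrix(A)
}

#' Extract the learned adjacency from a fitted model
#'
#' The trainable adjacency, rectified (absolute value) and symmetrized —
#' the form the propagation operator actually uses.
#'
#' @param object A fitted [dgcn_fit()] model.
#' @return An [adjacency_matrix()] with `is_learned = TRUE`.
#' @export
learned_adjacency <- function(object) {
  stopifnot(inherits(object, "dgcn"))
  adjacency_matrix(.adj_weights(object), object$channel_names,
                   initializer = object$adjacency_initial$initializer,
                   is_learned = TRUE)
}

#' Min-max normalize connection weights to [0, 1]
#'
#' Symmetrizes and rectifies, then rescales the off-diagonal entries
#' linearly so the weakest maps to 0 and the strongest to 1. A constant
#' off-diagonal (degenerate range) maps to all zeros. The diagonal is set
#' to 0: self-connections take no part in the ranking.
#'
#' @param A Matrix, [adjacency_matrix()] or fitted `"dgcn"` model.
#' @return n x n matrix with off-diagonal entries in `[0, 1]`, zero
#'   diagonal.
#' @export
normalize01 <- function(A) {
  w <- .adj_weights(A)
  w <- abs((w + t(w)) / 2)
  off <- w[upper.tri(w)]
  rng <- range(off)
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  if (diff(rng) > 0) {
    scaled <- (w - rng[1L]) / diff(rng)
    out[upper.tri(out)] <- scaled[upper.tri(scaled)]
    out <- out + t(out)
  }
  diag(out) <- 0
  out
}

#' Top-k strongest connections
#'
#' Ranks unordered channel pairs by normalized weight (descending); ties on
#' the k-th weight are broken lexicographically by channel names so the
#' ranking is deterministic.
#'
#' @param A Matrix, [adjacency_matrix()] or fitted `"dgcn"` model.
#' @param channel_names Labels (default: dimnames of `A` or the standard
#'   montage).
#' @param k Number of edges (default 10).
#' @param source Provenance tag, `"initial"` or `"learned"`, recorded on
#'   the result.
#' @return Object of class `"edge_ranking"`: a data.frame with columns
#'   `channel_i`, `channel_j`, `weight`, `local` (both endpoints in the same
#'   scalp region).
#' @export
top_edges <- function(A, channel_names = NULL, k = 10L,
                      source = c("learned", "initial")) {
  source <- match.arg(source)
  w <- normalize01(A)
  n <- nrow(w)
  if (is.null(channel_names)) {
    channel_names <- dimnames(w)[[1L]] %||% seed_channels(n)
  }
  if (k > n * (n - 1L) / 2L) stop("k exceeds the number of channel pairs")
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ni <- channel_names[ut[, 1L]]; nj <- channel_names[ut[, 2L]]
  df <- data.frame(channel_i = pmin(ni, nj), channel_j = pmax(ni, nj),
                   weight = w[ut], stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$channel_i, df$channel_j), ]
  df <- df[seq_len(k), ]
  rownames(df) <- NULL
  lobes <- channel_lobes(channel_names)
  df$local <- lobes[df$channel_i] == lobes[df$channel_j]
  structure(df, class = c("edge_ranking", "data.frame"),
            k = k, source = source)
}

#' @export
print.edge_ranking <- function(x, ...) {
  cat(sprintf("Top %d connections (%s adjacency):\n",
              attr(x, "k"), attr(x, "source")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Per-edge change between initial and learned connectivity
#'
#' Both matrices are min-max normalized to `[0, 1]` first; the table lists
#' every unordered channel pair with its initial weight, learned weight and
#' difference, sorted by absolute change.
#'
#' @param A_initial,A_learned Matrices, [adjacency_matrix()] objects or a
#'   fitted `"dgcn"` model (for `A_learned`).
#' @param channel_names Optional labels.
#' @return data.frame with columns `channel_i`, `channel_j`, `initial`,
#'   `learned`, `delta` and `n (n - 1) / 2` rows.
#' @export
asymmetry_delta <- function(A_initial, A_learned, channel_names = NULL) {
  wi <- normalize01(A_initial)
  wl <- normalize01(A_learned)
  stopifnot(all(dim(wi) == dim(wl)))
  n <- nrow(wi)
  if (is.null(channel_names)) {
    channel_names <- dimnames(wi)[[1L]] %||% seed_channels(n)
  }
  ut <- which(upper.tri(wi), arr.ind = TRUE)
  ni <- channel_names[ut[, 1L]]; nj <- channel_names[ut[, 2L]]
  df <- data.frame(channel_i = pmin(ni, nj), channel_j = pmax(ni, nj),
                   initial = wi[ut], learned = wl[ut],
                   delta = wl[ut] - wi[ut], stringsAsFactors = FALSE)
  df[order(-abs(df$delta)), ]
}

#' Write an edge table as TSV
#'
#' @param edges A data.frame ([top_edges()] or [asymmetry_delta()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
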