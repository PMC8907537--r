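# S3 methods for the fitted model object.

#' @export
print.dgcn <- function(x, ...) {
  cfg <- x$params$config
  cat("Dynamic-graph convolutional EEG emotion classifier\n")
  cat(sprintf("  channels: %d   bands: %d   classes: %d\n",
              cfg$n, cfg$f, x$n_classes))
  cat(sprintf("  GCN widths: %s   SRM: %s   fused width: %d\n",
              paste(cfg$gcn_dims, collapse = " -> "),
              if (cfg$use_srm) "on" else "off", cfg$fuse_width))
  cat(sprintf("  adjacency init: %s   epochs trained: %d\n",
              x$adjacency_initial$initializer, nrow(x$history)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
                last$loss, last$accuracy))
  }
  invisible(x)
}

#' @export
summary.dgcn <- function(object, ...) {
  ad <- asymmetry_delta(object$adjacency_initial, object)
  out <- list(model = object,
              top_learned = top_edges(object, k = min(10L, nrow(ad))),
              largest_changes = utils::head(ad, 5L))
  class(out) <- "summary.dgcn"
  out
}

#' @export
print.summary.dgcn <- function(x, ...) {
  print(x$model)
  cat("\n")
  print(x$top_learned)
  cat("\nLargest connection changes (normalized weights):\n")
  print(x$largest_changes, digits = 3)
  invisible(x)
}

#' Model coefficients: the learned adjacency
#'
#' For this model the scientifically meaningful "coefficients" are the
#' learned channel-connectivity weights; the network tensors are available
#' via `object$params$tensors`.
#'
#' @param object A fitted [dgcn_fit()] model.
#' @param ... Unused.
#' @return The learned adjacency weight matrix (rectified, symmetrized).
#' @export
coef.dgcn <- function(object, ...) {
  learned_adjacency(object)$weights
}

#' Plot the training history
#'
#' @param x A fitted [dgcn_fit()] model.
#' @param ... Passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.dgcn <- function(x, ...) {
  if (!nrow(x$history)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(old))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "loss", main = "Training loss", ...)
  plot(x$history$epoch, x$history$accuracy, type = "l", xlab = "epoch",
       ylab = "accuracy", main = "Training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}
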