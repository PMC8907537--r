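# Training: Adam jointly updating the network weights and the adjacency,
# trial-based splits, evaluation, per-subject summaries.

#' Initialize Adam state for one parameter array
#'
#' @param param Numeric array.
#' @return List with zero first/second moments `m`, `v` and step counter
#'   `t = 0`.
#' @export
adam_init <- function(param) {
  list(m = array(0, dim(param) %||% length(param)),
       v = array(0, dim(param) %||% length(param)), t = 0L)
}

#' One Adam update
#'
#' Textbook bias-corrected Adam:
#' `m <- b1 m + (1 - b1) g`, `v <- b2 v + (1 - b2) g^2`,
#' `param <- param - lr * m / (1 - b1^t) / (sqrt(v / (1 - b2^t)) + eps)`.
#'
#' @param param Numeric array.
#' @param grad Gradient, same shape.
#' @param state State from [adam_init()] (or a previous step).
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam constants (defaults 0.9, 0.999, 1e-8).
#' @return List with updated `param` and `state`.
#' @export
adam_step <- function(param, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (any(!is.finite(grad))) stop("non-finite gradient in adam_step")
  t <- state$t + 1L
  m <- beta1 * state$m + (1 - beta1) * grad
  v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps),
       state = list(m = m, v = v, t = t))
}

#' Training configuration
#'
#' Defaults follow the reference setup: Adam with `beta1 = 0.9`,
#' `beta2 = 0.999`, `eps = 1e-8`; learning rate 0.005 (midpoint of the
#' 0.001-0.01 range); L2 coefficient 0.01 (squared norm); dropout 0.7 after
#' FC1/FC2; batch size 16. `epochs` has no reference default and must be
#' chosen per problem.
#'
#' @param lr Learning rate in `[0.001, 0.01]` conventionally.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param l2_alpha L2 regularization coefficient.
#' @param l2_squared Penalize the squared norm (default) or the plain norm.
#' @param l2_include_adjacency Include the adjacency in the penalty.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param gcn_dims GCN layer widths (last must be 64).
#' @param use_srm Enable style recalibration (ablation switch).
#' @param leaky_slope Leaky-ReLU negative slope.
#' @param adjacency_init `"pcc"`, `"plv"` or `"random"` (used when no
#'   explicit adjacency is passed to [dgcn_fit()]).
#' @param beta1,beta2,eps Adam constants.
#' @param seed RNG seed governing initialization, shuffling and dropout.
#' @param verbose Print per-epoch loss.
#' @return Object of class `"dgcn_control"`.
#' @export
dgcn_control <- function(lr = 0.005, epochs = 60L, batch_size = 16L,
                         l2_alpha = 0.01, l2_squared = TRUE,
                         l2_include_adjacency = TRUE, dropout = 0.7,
                         gcn_dims = c(16L, 64L), use_srm = TRUE,
                         leaky_slope = 0.01, adjacency_init = "pcc",
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1L, dropout >= 0, dropout < 1, epochs >= 0L)
  structure(as.list(environment()), class = "dgcn_control")
}

.subset_featureset <- function(fs, sel) {
  eeg_featureset(fs$features[sel, , , drop = FALSE], fs$labels[sel],
                 fs$trial_index[sel], fs$band_names, fs$channel_names,
                 fs$subject_id)
}

#' Trial-based train/test split
#'
#' Assigns whole trials: the first `k_train` trials (by trial id) form the
#' training set, the next `k_test` (default: all remaining) the test set, so
#' no segment ever shares a trial across the split — the 9/6 and 16/8
#' protocols of the 15- and 24-trial sessions.
#'
#' @param fs An [eeg_featureset()].
#' @param k_train Number of training trials.
#' @param k_test Number of test trials (default: the rest).
#' @return List with `train` and `test` feature sets.
#' @export
split_trials <- function(fs, k_train, k_test = NULL) {
  trials <- sort(unique(fs$trial_index))
  if (k_train >= length(trials)) {
    stop(sprintf("need more than %d trials, have %d", k_train, length(trials)))
  }
  if (is.null(k_test)) k_test <- length(trials) - k_train
  if (k_train + k_test > length(trials)) {
    stop(sprintf("need %d trials, have %d", k_train + k_test, length(trials)))
  }
  tr_ids <- trials[seq_len(k_train)]
  te_ids <- trials[k_train + seq_len(k_test)]
  list(train = .subset_featureset(fs, fs$trial_index %in% tr_ids),
       test = .subset_featureset(fs, fs$trial_index %in% te_ids))
}

#' Fit the dynamic-graph convolutional emotion classifier
#'
#' Trains the full model — multi-layer GCN over a learnable channel
#' adjacency, style-recalibrated convolutional stack, fused softmax
#' classifier — by mini-batch Adam on the regularized cross-entropy,
#' updating the adjacency jointly with the network weights.
#'
#' @param x Training data: an [eeg_featureset()].
#' @param control A [dgcn_control()] configuration.
#' @param adjacency Optional initial adjacency ([adjacency_matrix()] or
#'   matrix); when `NULL` it is built from `x` by the initializer named in
#'   `control$adjacency_init`.
#' @return Object of class `"dgcn"`: the trained parameters, the initial
#'   adjacency, the per-epoch loss/accuracy history and the configuration.
#' @export
#' @examples
#' spec <- synthetic_spec(n_channels = 8, trials_per_class_per_subject = 2,
#'                        segments_per_trial = 5,
#'                        class_graphs = replicate(3, diag(8), simplify = FALSE))
#' fs <- generate_featureset(spec)$featureset
#' fit <- dgcn_fit(fs, dgcn_control(epochs = 2, batch_size = 8))
#' print(fit)
dgcn_fit <- function(x, control = dgcn_control(), adjacency = NULL) {
  stopifnot(inherits(x, "eeg_featureset"), inherits(control, "dgcn_control"))
  d <- dim(x$features)
  n <- d[2L]; f <- d[3L]
  n_classes <- max(x$labels) + 1L
  if (is.null(adjacency)) {
    adjacency <- switch(control$adjacency_init,
      pcc = pcc_adjacency(x),
      random = random_adjacency(n, seed = control$seed,
                                channel_names = x$channel_names),
      plv = stop("PLV initialization needs raw signals: pass `adjacency = plv_adjacency(rec)`"),
      stop("unknown adjacency_init: ", control$adjacency_init))
  }
  A0 <- if (inherits(adjacency, "eeg_adjacency")) adjacency else
    adjacency_matrix(adjacency, x$channel_names)
  params <- model_init(n, f, n_classes, A0, gcn_dims = control$gcn_dims,
                       use_srm = control$use_srm,
                       leaky_slope = control$leaky_slope,
                       dropout = control$dropout, seed = control$seed)
  N <- d[1L]
  states <- lapply(params$tensors, adam_init)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  X <- x$features
  labels <- x$labels
  if (control$epochs > 0L) {
    for (ep in seq_len(control$epochs)) {
      perm <- sample.int(N)
      starts <- seq(1L, N, by = control$batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + control$batch_size - 1L, N)]
        lg <- model_loss_grad(params, X[idx, , , drop = FALSE], labels[idx],
                              alpha = control$l2_alpha,
                              squared = control$l2_squared,
                              include_adjacency = control$l2_include_adjacency)
        if (!is.finite(lg$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        }
        for (nm in names(params$tensors)) {
          up <- adam_step(params$tensors[[nm]], lg$grads[[nm]], states[[nm]],
                          control$lr, control$beta1, control$beta2,
                          control$eps)
          params$tensors[[nm]] <- up$param
          states[[nm]] <- up$state
        }
        params$state <- lg$forward$new_state
        ep_loss <- ep_loss + lg$loss * length(idx)
        pred <- max.col(lg$probs) - 1L
        ep_correct <- ep_correct + sum(pred == labels[idx])
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / N,
                                  accuracy = ep_correct / N))
      if (control$verbose) {
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f",
                        ep, ep_loss / N, ep_correct / N))
      }
    }
  }
  structure(
    list(params = params, control = control, history = history,
         adjacency_initial = A0, n_classes = n_classes,
         channel_names = x$channel_names, band_names = x$band_names,
         call = match.call()),
    class = "dgcn")
}

#' Predict classes or probabilities from a fitted model
#'
#' @param object A fitted [dgcn_fit()] model.
#' @param newdata An [eeg_featureset()] or N x n x f array.
#' @param type `"class"` (0-based integer labels) or `"prob"`.
#' @param ... Unused.
#' @return Integer vector or N x C probability matrix.
#' @export
predict.dgcn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "eeg_featureset")) newdata$features else newdata
  if (length(dim(X)) == 2L) X <- array(X, c(1L, dim(X)))
  probs <- .forward_full(object$params, X, "eval")$probs
  if (type == "prob") probs else max.col(probs) - 1L
}

#' Evaluate a fitted model on a test set
#'
#' @param object A fitted [dgcn_fit()] model.
#' @param fs Test [eeg_featureset()].
#' @return List with `accuracy` (trace of the confusion matrix over total)
#'   and `confusion` (C x C matrix, rows = true class, columns = predicted).
#' @export
evaluate_model <- function(object, fs) {
  stopifnot(inherits(object, "dgcn"), inherits(fs, "eeg_featureset"))
  pred <- predict(object, fs, type = "class")
  C <- object$n_classes
  conf <- matrix(0L, C, C,
                 dimnames = list(true = 0:(C - 1L), predicted = 0:(C - 1L)))
  for (i in seq_along(pred)) {
    conf[fs$labels[i] + 1L, pred[i] + 1L] <- conf[fs$labels[i] + 1L, pred[i] + 1L] + 1L
  }
  list(accuracy = sum(diag(conf)) / sum(conf), confusion = conf)
}

#' Mean and standard deviation of per-subject accuracies
#'
#' @param accuracies Numeric vector, one accuracy per subject.
#' @return Named vector `c(mean, sd)`; `sd` is 0 for a single subject.
#' @export
subject_summary <- function(accuracies) {
  stopifnot(length(accuracies) >= 1L)
  s <- if (length(accuracies) == 1L) 0 else stats::sd(accuracies)
  c(mean = mean(accuracies), sd = s)
}
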