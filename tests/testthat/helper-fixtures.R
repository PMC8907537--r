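# Shared fixtures: tiny synthetic specs and edge-set helpers.

tiny_spec <- function(n_channels = 8L, n_classes = 3L, seed = 1L,
                      segments_per_trial = 6L, trials_per_class = 2L,
                      class_graphs = NULL) {
  synthetic_spec(n_channels = n_channels, n_classes = n_classes,
                 trials_per_class_per_subject = trials_per_class,
                 segments_per_trial = segments_per_trial,
                 class_graphs = class_graphs %||%
                   replicate(n_classes, diag(n_channels), simplify = FALSE),
                 seed = seed)
}

# the 62-channel 3-class benchmark used for recovery and ablation checks
benchmark_spec <- function(segments_per_trial = 120L, seed = 5L) {
  synthetic_spec(segments_per_trial = segments_per_trial, seed = seed)
}

benchmark_control <- function(epochs = 5L, seed = 2L, ...) {
  dgcn_control(epochs = epochs, seed = seed,
               l2_include_adjacency = FALSE, ...)
}

edge_key <- function(df) {
  paste(pmin(df$channel_i, df$channel_j), pmax(df$channel_i, df$channel_j))
}

top_overlap <- function(A_est, A_true, k = 10L) {
  length(intersect(edge_key(top_edges(A_est, k = k)),
                   edge_key(top_edges(A_true, k = k))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
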