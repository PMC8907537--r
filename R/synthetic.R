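# Synthetic EEG with class-conditional connectivity, used to exercise the
# whole pipeline: per-class ground-truth graphs drive either raw-signal
# synthesis (band-limited sources mixed through a matrix square root of the
# graph) or direct DE-style feature draws.

#' Nearest-correlation repair by eigenvalue clipping
#'
#' Clips negative eigenvalues of a symmetric matrix at zero and rescales the
#' diagonal back to 1, yielding a valid correlation matrix.
#'
#' @param C Symmetric matrix with unit diagonal (a target correlation
#'   pattern).
#' @return Positive-semidefinite correlation matrix with unit diagonal.
#' @export
nearest_psd <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  C2 <- e$vectors %*% (vals * t(e$vectors))
  d <- diag(C2)
  if (any(d <= 0)) stop("degenerate matrix: zero diagonal after PSD repair")
  dis <- 1 / sqrt(d)
  C2 <- C2 * outer(dis, dis)
  (C2 + t(C2)) / 2
}

.sym_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Default per-class band-power profiles
#'
#' Each class starts from a common 1/f-like base power per band and boosts
#' one band strongly (x1.8) and a second band mildly (x1.4), emulating
#' emotion-dependent shifts of spectral power.
#'
#' @param n_classes Number of classes.
#' @param n_bands Number of bands (default 5).
#' @return n_classes x n_bands positive matrix.
#' @export
default_band_powers <- function(n_classes, n_bands = 5L) {
  base <- c(8, 6, 5, 4, 3)[seq_len(n_bands)]
  bp <- matrix(rep(base, each = n_classes), n_classes, n_bands)
  for (k in seq_len(n_classes)) {
    b1 <- ((k - 1L) %% n_bands) + 1L
    b2 <- ((k + 1L) %% n_bands) + 1L
    bp[k, b1] <- bp[k, b1] * 1.8
    bp[k, b2] <- bp[k, b2] * 1.4
  }
  bp
}

#' Default ground-truth class connectivity graphs
#'
#' All classes share a weak heterogeneous background (i.i.d. Uniform(0.02,
#' 0.20) per pair, as real correlation backgrounds are never constant) plus
#' a common backbone of strong edges with distinct weights spread over
#' 0.55-0.85, so the ranking of the strongest connections is well defined;
#' each class additionally carries its own disjoint set of class-specific
#' edges (weight 0.6). Strong edges sit on disjoint channel pairs; the
#' matrices are passed through [nearest_psd()] at generation time.
#'
#' @param n_channels Number of channels.
#' @param n_classes Number of classes.
#' @param n_shared Shared strong edges; by default half the available
#'   disjoint-pair budget (15 for the 62-channel cap).
#' @param n_specific Class-specific edges per class; by default the
#'   remaining budget split across classes (5 for 62 channels, 3 classes).
#' @param seed RNG seed for edge placement.
#' @return List of `n_classes` symmetric matrices with unit diagonal and
#'   entries in `[0, 1]`.
#' @export
default_class_graphs <- function(n_channels = 62L, n_classes = 3L,
                                 n_shared = NULL, n_specific = NULL,
                                 seed = 99L) {
  budget <- n_channels %/% 2L            # disjoint channel pairs available
  if (is.null(n_shared)) n_shared <- max(1L, budget %/% 2L)
  if (is.null(n_specific)) {
    n_specific <- max(0L, (budget - n_shared) %/% n_classes)
  }
  need <- 2L * (n_shared + n_classes * n_specific)
  if (need > n_channels) {
    stop(sprintf("need %d distinct channels for disjoint edges, have %d",
                 need, n_channels))
  }
  set.seed(seed)
  chans <- sample.int(n_channels, need)
  take_pairs <- function(k) {
    out <- matrix(chans[seq_len(2L * k)], ncol = 2L, byrow = TRUE)
    chans <<- chans[-seq_len(2L * k)]
    out
  }
  shared <- take_pairs(n_shared)
  base <- matrix(0, n_channels, n_channels)
  base[upper.tri(base)] <- stats::runif(n_channels * (n_channels - 1L) / 2L,
                                        0.02, 0.20)
  base <- base + t(base)
  diag(base) <- 1
  backbone_w <- seq(0.85, 0.55, length.out = n_shared)
  for (r in seq_len(nrow(shared))) {
    base[shared[r, 1L], shared[r, 2L]] <- base[shared[r, 2L], shared[r, 1L]] <-
      backbone_w[r]
  }
  lapply(seq_len(n_classes), function(k) {
    g <- base
    own <- matrix(chans[seq_len(2L * n_specific) + (k - 1L) * 2L * n_specific],
                  ncol = 2L, byrow = TRUE)
    for (r in seq_len(nrow(own))) {
      g[own[r, 1L], own[r, 2L]] <- g[own[r, 2L], own[r, 1L]] <- 0.6
    }
    g
  })
}

#' Specification for synthetic EEG generation
#'
#' Bundles every knob of the generator: geometry (channels, classes,
#' subjects, trials, segments), signal parameters (segment length, sampling
#' rate, sensor noise), the per-class ground-truth connectivity graphs and
#' per-class band-power profiles, and the seed.
#'
#' @param n_channels Channels (default 62, the standard cap).
#' @param n_classes Emotion classes (default 3).
#' @param n_subjects Subjects (default 1).
#' @param trials_per_class_per_subject Trials per class per subject
#'   (default 5, giving 15 trials per subject for 3 classes).
#' @param segments_per_trial Non-overlapping segments per trial (default 40).
#' @param segment_length Segment length in seconds (default 1).
#' @param sampling_rate Hz (default 200).
#' @param class_graphs List of per-class symmetric connectivity matrices with
#'   unit diagonal and entries in `[0, 1]`; defaults to
#'   [default_class_graphs()].
#' @param noise_sd Additive sensor-noise standard deviation relative to unit
#'   source variance (default 0.05; raw-signal path only).
#' @param feature_scale Within-class standard deviation of the DE-style
#'   features in nats (default 0.6); the channel correlation structure is
#'   the class graph regardless of scale.
#' @param band_powers n_classes x n_bands positive matrix; defaults to
#'   [default_band_powers()].
#' @param seed Integer RNG seed.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_channels = 62L, n_classes = 3L, n_subjects = 1L,
                           trials_per_class_per_subject = 5L,
                           segments_per_trial = 40L,
                           segment_length = 1, sampling_rate = 200,
                           class_graphs = NULL, noise_sd = 0.05,
                           feature_scale = 0.6, band_powers = NULL,
                           seed = 1L) {
  if (is.null(class_graphs)) {
    class_graphs <- default_class_graphs(n_channels, n_classes)
  }
  if (is.null(band_powers)) band_powers <- default_band_powers(n_classes)
  stopifnot(length(class_graphs) == n_classes,
            all(vapply(class_graphs, function(g) {
              nrow(g) == n_channels && ncol(g) == n_channels &&
                max(abs(g - t(g))) < 1e-8 && all(diag(g) == 1) &&
                all(g >= 0) && all(g <= 1)
            }, logical(1L))),
            all(band_powers > 0), nrow(band_powers) == n_classes,
            noise_sd >= 0, feature_scale > 0, segment_length > 0,
            sampling_rate > 0,
            trials_per_class_per_subject >= 1L, segments_per_trial >= 1L)
  structure(list(n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 n_subjects = as.integer(n_subjects),
                 trials_per_class_per_subject = as.integer(trials_per_class_per_subject),
                 segments_per_trial = as.integer(segments_per_trial),
                 segment_length = segment_length,
                 sampling_rate = sampling_rate,
                 class_graphs = class_graphs, noise_sd = noise_sd,
                 feature_scale = feature_scale, band_powers = band_powers,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.trial_table <- function(spec) {
  # interleave classes so a "first k trials" split sees every class
  per_subj <- spec$trials_per_class_per_subject * spec$n_classes
  do.call(rbind, lapply(seq_len(spec$n_subjects), function(s) {
    data.frame(subject = s,
               trial = seq_len(per_subj),
               class = rep(seq_len(spec$n_classes) - 1L,
                           times = spec$trials_per_class_per_subject))
  }))
}

.repaired_graphs <- function(spec) {
  lapply(seq_along(spec$class_graphs), function(k) {
    g <- nearest_psd(spec$class_graphs[[k]])
    e <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    if (min(e) < -1e-8) stop(sprintf("class %d graph not PSD after repair", k - 1L))
    g
  })
}

#' Generate raw synthetic EEG recordings
#'
#' For each trial, independent per-channel sources are built as sums of
#' band-limited Gaussian noise (one component per band, variance set by the
#' class's band power), then mixed through the symmetric matrix square root
#' of the trial's class graph (repaired to a correlation matrix), so the
#' expected inter-channel |PCC| approximates the graph. White sensor noise
#' of sd `noise_sd` (relative to unit source variance) is added.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `recordings` (list of [eeg_recording()], one per trial)
#'   and `truth` (class graphs and the subject/trial/class table).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  graphs <- .repaired_graphs(spec)
  mixers <- lapply(graphs, .sym_sqrt)
  tt <- .trial_table(spec)
  bands <- eeg_bands()
  n_samp <- as.integer(round(spec$segments_per_trial * spec$segment_length *
                               spec$sampling_rate))
  ch <- seed_channels(spec$n_channels)
  recs <- vector("list", nrow(tt))
  for (r in seq_len(nrow(tt))) {
    k <- tt$class[r] + 1L
    bp <- spec$band_powers[k, ]
    src <- matrix(0, spec$n_channels, n_samp)
    for (b in seq_len(nrow(bands))) {
      white <- matrix(stats::rnorm(spec$n_channels * n_samp),
                      spec$n_channels, n_samp)
      bl <- bandpass_filter(white, bands$low[b], bands$high[b],
                            spec$sampling_rate)
      bl <- bl / apply(bl, 1L, stats::sd)       # unit variance per channel
      src <- src + sqrt(bp[b]) * bl
    }
    src <- src / sqrt(sum(bp))                  # unit total source variance
    x <- mixers[[k]] %*% src +
      spec$noise_sd * matrix(stats::rnorm(spec$n_channels * n_samp),
                             spec$n_channels, n_samp)
    recs[[r]] <- eeg_recording(x, spec$sampling_rate, ch,
                               subject_id = tt$subject[r],
                               trial_id = tt$trial[r],
                               label = tt$class[r])
  }
  list(recordings = recs,
       truth = list(class_graphs = graphs, trials = tt))
}

#' Generate DE-style feature sets directly
#'
#' Bypasses signal synthesis: per segment and band, channel features are
#' drawn from a multivariate Gaussian whose channel correlation is the
#' (repaired) class graph, whose per-channel standard deviation is
#' `feature_scale` nats, and whose mean is the log of that class's band
#' power.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `featuresets` (one [eeg_featureset()] per subject;
#'   `featureset` is attached for the single-subject case) and `truth`.
#' @export
generate_featureset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  graphs <- .repaired_graphs(spec)
  mixers <- lapply(graphs, .sym_sqrt)
  tt <- .trial_table(spec)
  n_bands <- ncol(spec$band_powers)
  S <- spec$segments_per_trial
  ch <- seed_channels(spec$n_channels)
  sets <- lapply(seq_len(spec$n_subjects), function(s) {
    rows <- tt[tt$subject == s, ]
    feats <- array(NA_real_, c(nrow(rows) * S, spec$n_channels, n_bands))
    labels <- integer(nrow(rows) * S)
    trial_index <- integer(nrow(rows) * S)
    for (r in seq_len(nrow(rows))) {
      k <- rows$class[r] + 1L
      idx <- ((r - 1L) * S + 1L):(r * S)
      for (b in seq_len(n_bands)) {
        z <- matrix(stats::rnorm(spec$n_channels * S), spec$n_channels, S)
        feats[idx, , b] <- spec$feature_scale * t(mixers[[k]] %*% z) +
          log(spec$band_powers[k, b])
      }
      labels[idx] <- rows$class[r]
      trial_index[idx] <- rows$trial[r]
    }
    eeg_featureset(feats, labels, trial_index,
                   band_names = eeg_bands()$name[seq_len(n_bands)],
                   channel_names = ch, subject_id = s)
  })
  out <- list(featuresets = sets,
              truth = list(class_graphs = graphs, trials = tt))
  if (spec$n_subjects == 1L) out$featureset <- sets[[1L]]
  out
}
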