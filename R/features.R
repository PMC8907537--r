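# Differential-entropy band features: band definitions, segmentation,
# zero-phase band-pass filtering and the Gaussian plug-in DE estimator.

#' The five classical EEG frequency bands
#'
#' Delta 1-4, Theta 4-8, Alpha 8-12, Beta 12-30 and Gamma 30-64 Hz, the band
#' set conventionally used for differential-entropy emotion features.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 12, 30),
    high = c(4, 8, 12, 30, 64),
    stringsAsFactors = FALSE
  )
}

#' Construct a raw EEG recording object
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Channel labels; defaults to `seed_channels(nrow(signal))`.
#' @param subject_id,trial_id Integer annotations.
#' @param label Class label (0-based integer) or `NA` when unlabeled.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_names = NULL,
                          subject_id = 1L, trial_id = 1L, label = NA_integer_) {
  signal <- as.matrix(signal)
  if (is.null(channel_names)) channel_names <- seed_channels(nrow(signal))
  stopifnot(is.numeric(signal), sampling_rate > 0,
            length(channel_names) == nrow(signal))
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channel_names = channel_names, subject_id = as.integer(subject_id),
         trial_id = as.integer(trial_id), label = label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), subject %d, trial %d, label %s\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate, x$subject_id, x$trial_id,
              as.character(x$label)))
  invisible(x)
}

#' Split a recording into fixed-length non-overlapping segments
#'
#' Contiguous windows of `window` seconds; a trailing partial window is
#' dropped.
#'
#' @param rec An [eeg_recording()].
#' @param window Window length in seconds (default 1 s).
#' @return List of channels x samples matrices (possibly empty, with a
#'   warning, when the recording is shorter than one window).
#' @export
segment_signal <- function(rec, window = 1) {
  stopifnot(inherits(rec, "eeg_recording"), window > 0)
  len <- as.integer(floor(window * rec$sampling_rate))
  if (len < 2L) stop("window too short: fewer than 2 samples per segment")
  n <- ncol(rec$signal)
  k <- n %/% len
  if (k == 0L) {
    warning("recording shorter than one window; returning no segments")
    return(list())
  }
  lapply(seq_len(k), function(s) rec$signal[, ((s - 1L) * len + 1L):(s * len), drop = FALSE])
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`),
#' so the output is band-limited with no phase distortion and the same
#' length as the input.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param low,high Band edges in Hz; `0 < low < high < sampling_rate / 2`.
#' @param sampling_rate Sampling rate in Hz.
#' @param order Butterworth order (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, low, high, sampling_rate, order = 4L) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high)) stop("band edges must satisfy 0 < low < high")
  if (high >= nyq) stop(sprintf("band edge %g Hz >= Nyquist %g Hz", high, nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  ff <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) t(apply(x, 1L, ff)) else ff(x)
}

#' Differential entropy of a band-limited segment
#'
#' The Gaussian plug-in estimator `0.5 * log(2 * pi * e * sigma^2)` in nats,
#' with `sigma^2` the population-convention sample variance (divide by n) of
#' the segment. For a segment that really is Gaussian this converges to the
#' differential entropy of its distribution.
#'
#' @param x Numeric vector (one channel of one band-filtered segment).
#' @return DE value in nats (finite scalar).
#' @export
#' @examples
#' differential_entropy(rnorm(1000))  # about 0.5 * log(2 * pi * exp(1))
differential_entropy <- function(x) {
  if (length(x) < 2L) stop("segment must have at least 2 samples")
  v <- mean((x - mean(x))^2)
  if (v <= 0) stop("zero-variance segment: differential entropy is -Inf")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Construct a feature set
#'
#' @param features segments x channels x bands numeric array (nats).
#' @param labels Integer vector, 0-based class index per segment.
#' @param trial_index Integer vector, trial id per segment.
#' @param band_names Character vector of band labels.
#' @param channel_names Character vector of channel labels.
#' @param subject_id Integer annotation.
#' @return Object of class `"eeg_featureset"`.
#' @export
eeg_featureset <- function(features, labels, trial_index,
                           band_names = eeg_bands()$name,
                           channel_names = NULL, subject_id = 1L) {
  stopifnot(is.array(features), length(dim(features)) == 3L,
            dim(features)[1] == length(labels),
            dim(features)[1] == length(trial_index),
            all(is.finite(features)))
  if (is.null(channel_names)) channel_names <- seed_channels(dim(features)[2])
  stopifnot(length(channel_names) == dim(features)[2],
            length(band_names) == dim(features)[3])
  labels <- as.integer(labels)
  if (length(labels) && any(labels < 0L)) stop("labels must be 0-based nonnegative class indices")
  structure(
    list(features = features, labels = labels,
         trial_index = as.integer(trial_index),
         band_names = band_names, channel_names = channel_names,
         subject_id = as.integer(subject_id)),
    class = "eeg_featureset"
  )
}

#' @export
print.eeg_featureset <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<eeg_featureset> %d segments x %d channels x %d bands, %d trials, %d classes\n",
              d[1], d[2], d[3], length(unique(x$trial_index)),
              length(unique(x$labels))))
  invisible(x)
}

#' Extract differential-entropy band features from a recording
#'
#' Band-pass filters the whole recording per band (zero-phase, so no
#' segment-boundary transients), cuts it into non-overlapping windows and
#' computes the Gaussian plug-in DE per segment, channel and band.
#' Optionally smooths each channel/band DE series across segments within the
#' trial with a centred moving average.
#'
#' @param rec An [eeg_recording()].
#' @param window Segment length in seconds.
#' @param bands Band table as returned by [eeg_bands()].
#' @param smoothing `"none"` or `"moving_average"`.
#' @param k Moving-average half-width parameter: window of `k` segments
#'   (k = 1 is the identity).
#' @param order Butterworth order passed to [bandpass_filter()].
#' @return An [eeg_featureset()] with one row per segment.
#' @export
extract_features <- function(rec, window = 1, bands = eeg_bands(),
                             smoothing = c("none", "moving_average"),
                             k = 3L, order = 4L) {
  smoothing <- match.arg(smoothing)
  stopifnot(inherits(rec, "eeg_recording"))
  len <- as.integer(floor(window * rec$sampling_rate))
  n_seg <- ncol(rec$signal) %/% len
  if (n_seg == 0L) stop("recording shorter than one window")
  n_ch <- nrow(rec$signal)
  n_bd <- nrow(bands)
  feats <- array(NA_real_, c(n_seg, n_ch, n_bd))
  for (b in seq_len(n_bd)) {
    filt <- bandpass_filter(rec$signal, bands$low[b], bands$high[b],
                            rec$sampling_rate, order = order)
    for (s in seq_len(n_seg)) {
      idx <- ((s - 1L) * len + 1L):(s * len)
      seg <- filt[, idx, drop = FALSE]
      mu <- rowMeans(seg)
      v <- rowMeans((seg - mu)^2)
      if (any(v <= 0)) stop("zero-variance band segment encountered")
      feats[s, , b] <- 0.5 * log(2 * pi * exp(1) * v)
    }
  }
  if (smoothing == "moving_average" && k > 1L) {
    kern <- rep(1 / k, k)
    for (c in seq_len(n_ch)) for (b in seq_len(n_bd)) {
      feats[, c, b] <- stats::filter(feats[, c, b], kern, sides = 2L) |>
        (\(z) { z[is.na(z)] <- feats[, c, b][is.na(z)]; as.numeric(z) })()
    }
  }
  eeg_featureset(feats,
                 labels = rep(if (is.na(rec$label)) 0L else as.integer(rec$label), n_seg),
                 trial_index = rep(rec$trial_id, n_seg),
                 band_names = bands$name,
                 channel_names = rec$channel_names,
                 subject_id = rec$subject_id)
}

#' Bind feature sets from several trials into one
#'
#' @param fs_list List of [eeg_featureset()] objects with identical channel
#'   and band layout.
#' @return A single combined [eeg_featureset()].
#' @export
bind_featuresets <- function(fs_list) {
  stopifnot(length(fs_list) >= 1L)
  d <- dim(fs_list[[1L]]$features)
  feats <- do.call(rbind, lapply(fs_list, function(f) {
    matrix(f$features, nrow = dim(f$features)[1L])
  }))
  feats <- array(feats, c(nrow(feats), d[2], d[3]))
  eeg_featureset(feats,
                 labels = unlist(lapply(fs_list, `[[`, "labels")),
                 trial_index = unlist(lapply(fs_list, `[[`, "trial_index")),
                 band_names = fs_list[[1L]]$band_names,
                 channel_names = fs_list[[1L]]$channel_names,
                 subject_id = fs_list[[1L]]$subject_id)
}
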