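# Minimal MAT v5 container IO for the feature-file dialect used by the
# 62-channel emotion datasets: one double array per trial, shape
# channels x segments x bands, plus a per-trial label vector. Only
# double-precision real arrays (up to 3-D) are supported — that is all the
# dialect needs.

.MI_INT8 <- 1L; .MI_INT32 <- 5L; .MI_UINT32 <- 6L; .MI_DOUBLE <- 9L
.MI_MATRIX <- 14L; .MX_DOUBLE_CLASS <- 6L

.pad8 <- function(n) (8L - n %% 8L) %% 8L

.mat5_var_bytes <- function(name, a) {
  dims <- dim(a) %||% c(1L, length(a))
  if (length(dims) == 1L) dims <- c(1L, dims)
  nb <- charToRaw(name)
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # array flags
  w32(c(.MI_UINT32, 8L, .MX_DOUBLE_CLASS, 0L))
  # dimensions
  w32(c(.MI_INT32, 4L * length(dims)))
  w32(dims)
  writeBin(raw(.pad8(4L * length(dims))), con)
  # name
  w32(c(.MI_INT8, length(nb)))
  writeBin(nb, con)
  writeBin(raw(.pad8(length(nb))), con)
  # real data
  w32(c(.MI_DOUBLE, 8L * length(a)))
  writeBin(as.double(a), con, size = 8L, endian = "little")
  rawConnectionValue(con)
}

#' Write a feature set as a MAT v5 trial-per-array container
#'
#' Writes one double array per trial named `de_trial<t>` with shape
#' channels x segments x bands, plus a `label` row vector holding each
#' trial's class. This is the layout [read_seed_features()] consumes.
#'
#' @param fs An [eeg_featureset()]; must contain at least one segment.
#' @param path Output file path (`.mat`).
#' @return `path`, invisibly.
#' @export
write_seed_features <- function(fs, path) {
  stopifnot(inherits(fs, "eeg_featureset"))
  if (dim(fs$features)[1L] == 0L) stop("empty feature set: refusing to write")
  trials <- sort(unique(fs$trial_index))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, eegdgcn feature container, created %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8L), con)                                    # subsys offset
  writeBin(as.integer(c(256L)), con, size = 2L, endian = "little")  # 0x0100
  writeBin(charToRaw("IM"), con)
  labels <- numeric(length(trials))
  for (i in seq_along(trials)) {
    sel <- fs$trial_index == trials[i]
    a <- aperm(fs$features[sel, , , drop = FALSE], c(2L, 1L, 3L))
    labels[i] <- fs$labels[sel][1L]
    body <- .mat5_var_bytes(sprintf("de_trial%d", trials[i]), a)
    writeBin(as.integer(c(.MI_MATRIX, length(body))), con, size = 4L,
             endian = "little")
    writeBin(body, con)
  }
  body <- .mat5_var_bytes("label", labels)
  writeBin(as.integer(c(.MI_MATRIX, length(body))), con, size = 4L,
           endian = "little")
  writeBin(body, con)
  invisible(path)
}

.read_tag <- function(con) {
  raw4 <- readBin(con, "raw", 4L)
  if (length(raw4) < 4L) return(NULL)
  small <- readBin(raw4[3:4], "integer", 1L, size = 2L, endian = "little")
  type <- readBin(raw4[1:2], "integer", 1L, size = 2L, endian = "little")
  if (small != 0L) {                     # small element: data packed in tag
    data <- readBin(con, "raw", 4L)
    list(type = type, nbytes = small, small = TRUE, data = data[seq_len(small)])
  } else {
    nbytes <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    list(type = type, nbytes = nbytes, small = FALSE)
  }
}

.read_mat5_element <- function(raw_body) {
  con <- rawConnection(raw_body, "rb")
  on.exit(close(con))
  grab <- function() {
    tag <- .read_tag(con)
    if (is.null(tag)) return(NULL)
    if (tag$small) return(tag)
    tag$data <- readBin(con, "raw", tag$nbytes)
    readBin(con, "raw", .pad8(tag$nbytes))
    tag
  }
  flags <- grab()
  if (is.null(flags)) return(NULL)
  cls <- readBin(flags$data[1L], "integer", 1L, size = 1L)
  if (cls != .MX_DOUBLE_CLASS) return(NULL)       # unsupported class: skip
  dims_el <- grab()
  dims <- readBin(dims_el$data, "integer", dims_el$nbytes / 4L, size = 4L,
                  endian = "little")
  name_el <- grab()
  name <- rawToChar(name_el$data)
  data_el <- grab()
  vals <- readBin(data_el$data, "double", data_el$nbytes / 8L, size = 8L,
                  endian = "little")
  a <- if (length(dims) > 2L || (length(dims) == 2L && all(dims > 1L))) {
    array(vals, dims)
  } else as.numeric(vals)
  stats::setNames(list(a), name)
}

#' Read a MAT v5 file of double arrays
#'
#' Parses the subset of the MAT v5 format this package writes: real
#' double-precision arrays. Unsupported variable classes are skipped.
#'
#' @param path File path.
#' @return Named list of numeric vectors/arrays.
#' @export
read_mat5 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 124L)
  ver <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (ver != 256L || magic != "IM") stop("not a little-endian MAT v5 file")
  out <- list()
  repeat {
    tag <- .read_tag(con)
    if (is.null(tag)) break
    body <- readBin(con, "raw", tag$nbytes)
    if (tag$type == .MI_MATRIX) {
      el <- .read_mat5_element(body)
      if (!is.null(el)) out <- c(out, el)
    }
  }
  out
}

#' Read a trial-per-array feature container
#'
#' Inverse of [write_seed_features()]: collects `de_trial<t>` arrays
#' (channels x segments x bands) and the `label` vector into one
#' [eeg_featureset()]. Label codes containing negatives (the -1/0/1
#' convention of the 3-class distribution) are remapped to contiguous
#' 0-based classes.
#'
#' @param path File path.
#' @param channel_names Optional channel labels (default: standard montage).
#' @param subject_id Integer annotation attached to the result.
#' @return An [eeg_featureset()].
#' @export
read_seed_features <- function(path, channel_names = NULL, subject_id = 1L) {
  vars <- read_mat5(path)
  tn <- grep("^de_trial[0-9]+$", names(vars), value = TRUE)
  if (!length(tn)) stop("no de_trial<t> arrays found in ", path)
  ids <- as.integer(sub("^de_trial", "", tn))
  ord <- order(ids)
  tn <- tn[ord]; ids <- ids[ord]
  labels_raw <- as.numeric(vars$label)
  if (length(labels_raw) != length(tn)) stop("label vector does not match trial count")
  if (any(labels_raw < 0)) {
    labels_raw <- as.integer(factor(labels_raw, levels = sort(unique(labels_raw)))) - 1L
  }
  per_trial <- lapply(seq_along(tn), function(i) {
    a <- vars[[tn[i]]]
    if (length(dim(a)) != 3L) stop("trial array must be channels x segments x bands")
    aperm(a, c(2L, 1L, 3L))          # -> segments x channels x bands
  })
  feats <- do.call(rbind, lapply(per_trial, function(a) matrix(a, nrow = dim(a)[1L])))
  d <- dim(per_trial[[1L]])
  feats <- array(feats, c(nrow(feats), d[2L], d[3L]))
  eeg_featureset(feats,
                 labels = rep(as.integer(labels_raw), vapply(per_trial, function(a) dim(a)[1L], 1L)),
                 trial_index = rep(ids, vapply(per_trial, function(a) dim(a)[1L], 1L)),
                 band_names = paste0("band", seq_len(d[3L])),
                 channel_names = channel_names %||% seed_channels(d[2L]),
                 subject_id = subject_id)
}
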