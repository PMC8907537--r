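# Plain-text container for raw recordings: a TSV of samples x channels with
# the metadata in '#key<TAB>value' comment lines.

#' Write a recording as a plain TSV container
#'
#' Header comment lines (`#sampling_rate`, `#subject_id`, `#trial_id`,
#' `#label`) followed by a samples x channels table with channel names as
#' column headers.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sampling_rate\t%.10g", rec$sampling_rate),
               sprintf("#subject_id\t%d", rec$subject_id),
               sprintf("#trial_id\t%d", rec$trial_id),
               sprintf("#label\t%s", as.character(rec$label))), con)
  utils::write.table(
    stats::setNames(as.data.frame(t(rec$signal)), rec$channel_names),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording_tsv()]
#'
#' @param path File path.
#' @return An [eeg_recording()].
#' @export
read_recording_tsv <- function(path) {
  lines <- readLines(path, n = 16L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", check.names = FALSE)
  eeg_recording(t(as.matrix(tab)),
                sampling_rate = as.numeric(meta[["sampling_rate"]]),
                channel_names = colnames(tab),
                subject_id = as.integer(meta[["subject_id"]]),
                trial_id = as.integer(meta[["trial_id"]]),
                label = if (meta[["label"]] == "NA") NA_integer_ else
                  as.integer(meta[["label"]]))
}
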