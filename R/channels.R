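# 62-channel montage used by ESI NeuroScan caps (10-20 extended layout).
.SEED_CHANNELS <- c(
  "FP1", "FPZ", "FP2", "AF3", "AF4",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
  "CB1", "O1", "OZ", "O2", "CB2"
)

.LOBE_PATTERNS <- list(
  prefrontal = "^(FP|AF)",
  frontal    = "^F[0-9Z]",
  frontotemporal = "^FT",
  frontocentral  = "^FC",
  temporal   = "^(T|TP)[0-9]",
  central    = "^C[0-9Z]",
  centroparietal = "^CP",
  parietal   = "^P[0-9Z]",
  parietooccipital = "^PO",
  occipital  = "^(O|CB)[0-9Z]"
)

#' Standard 62-channel EEG montage names
#'
#' Channel labels for the 62-electrode 10-20-extended cap used by the
#' emotion datasets this package emulates, in their conventional order.
#'
#' @param n Number of channels requested. For `n = 62` the standard labels
#'   are returned; for other `n` generic labels `CH1..CHn` are generated.
#' @return Character vector of `n` channel names.
#' @export
#' @examples
#' head(seed_channels())
seed_channels <- function(n = 62L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 62L) .SEED_CHANNELS else paste0("CH", seq_len(n))
}

#' Lobe annotation for EEG channel names
#'
#' Maps channel labels to a coarse scalp-region ("lobe") annotation used to
#' classify learned connections as local (both endpoints in one region) or
#' global. The mapping is a plain named vector so it can be edited or
#' replaced.
#'
#' @param channels Character vector of channel names.
#' @return Named character vector: region per channel (`"other"` when no
#'   pattern matches).
#' @export
#' @examples
#' channel_lobes(c("FP1", "T7", "OZ"))
channel_lobes <- function(channels = seed_channels()) {
  out <- rep("other", length(channels))
  up <- toupper(channels)
  for (lobe in names(.LOBE_PATTERNS)) {
    hit <- grepl(.LOBE_PATTERNS[[lobe]], up) & out == "other"
    out[hit] <- lobe
  }
  names(out) <- channels
  out
}
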