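#' Standard 32-channel 10-20 montage
#'
#' Channel names of the standard 32-electrode extended 10-20 layout used by
#' common 32-channel EEG caps (reference electrode excluded). Row order of
#' every signal matrix and MI matrix in this package follows this vector
#' unless a custom montage is supplied.
#'
#' @format Character vector of 32 channel names.
#' @export
montage_32 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FT9", "FC5", "FC1", "FC2", "FC6", "FT10",
  "T7", "C3", "Cz", "C4", "T8",
  "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8",
  "O1", "Oz", "O2"
)

#' Construct a continuous multichannel recording
#'
#' A recording bundles a channels-by-samples signal matrix (microvolts), its
#' sampling rate, ordered channel names, and timestamped event annotations.
#' This is the substrate every phase/amplitude extraction works on.
#'
#' @param signal Numeric matrix, channels in rows, samples in columns.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one unique name per signal row.
#' @param annotations Tibble with columns `label`, `time_s` and optionally
#'   `trial`; times must lie within the recording.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(signal, fs_hz, channel_names,
                          annotations = empty_annotations()) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  stopifnot(is.numeric(signal), is.numeric(fs_hz), length(fs_hz) == 1L, fs_hz > 0)
  if (length(channel_names) != nrow(signal)) {
    stop("`channel_names` must have one entry per signal row", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  annotations <- tibble::as_tibble(annotations)
  dur <- ncol(signal) / fs_hz
  if (nrow(annotations) > 0L) {
    stopifnot(all(c("label", "time_s") %in% names(annotations)))
    bad <- annotations$time_s < 0 | annotations$time_s > dur
    if (any(bad)) stop("annotation times outside [0, duration]", call. = FALSE)
  }
  rownames(signal) <- channel_names
  structure(
    list(signal = signal, fs_hz = fs_hz,
         channel_names = as.character(channel_names),
         annotations = annotations),
    class = "eeg_recording"
  )
}

empty_annotations <- function() {
  tibble::tibble(label = character(), time_s = numeric(), trial = integer())
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d annotations\n",
              nrow(x$signal), ncol(x$signal), x$fs_hz,
              duration_s(x), nrow(x$annotations)))
  invisible(x)
}

duration_s <- function(recording) ncol(recording$signal) / recording$fs_hz

channel_index <- function(recording, channel) {
  idx <- match(channel, recording$channel_names)
  if (anyNA(idx)) {
    stop("unknown channel(s): ", paste(channel[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}
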