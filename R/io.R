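#' Write a recording as raw matrix + JSON sidecar (+ annotations TSV)
#'
#' The signal is stored as little-endian float64, channel-major (all samples
#' of channel 1, then channel 2, ...), in `<prefix>.dat`. A JSON sidecar
#' `<prefix>.json` records `fs_hz`, `channel_names`, `n_samples`, `dtype`,
#' `byte_order`, `unit` and `order`; annotations go to
#' `<prefix>_annotations.tsv` (`label`, `time_s`, `trial`).
#'
#' @param recording An `eeg_recording`.
#' @param prefix Output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$signal)), con, size = 8L, endian = "little")
  meta <- list(fs_hz = recording$fs_hz,
               channel_names = recording$channel_names,
               n_samples = ncol(recording$signal),
               dtype = "float64", byte_order = "little",
               unit = "uV", order = "channel_major")
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(recording$annotations) > 0L) {
    readr::write_tsv(recording$annotations, paste0(prefix, "_annotations.tsv"))
  }
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix Path prefix of the `.dat` / `.json` (and optional
#'   `_annotations.tsv`) files.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(prefix) {
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("fs_hz", "channel_names", "n_samples")) {
    if (is.null(meta[[key]])) stop("sidecar missing key: ", key, call. = FALSE)
  }
  n_ch <- length(meta$channel_names)
  dat_path <- paste0(prefix, ".dat")
  vals <- readBin(dat_path, "double", n = n_ch * meta$n_samples, size = 8L,
                  endian = if (identical(meta$byte_order, "big")) "big" else "little")
  if (length(vals) != n_ch * meta$n_samples) {
    stop("signal file length does not match sidecar channel count x n_samples",
         call. = FALSE)
  }
  sig <- t(matrix(vals, nrow = meta$n_samples, ncol = n_ch))
  ann_path <- paste0(prefix, "_annotations.tsv")
  ann <- if (file.exists(ann_path)) {
    readr::read_tsv(ann_path, show_col_types = FALSE)
  } else {
    empty_annotations()
  }
  new_recording(sig, meta$fs_hz, meta$channel_names, ann)
}

#' Write / read a trial-level behaviour table as TSV
#'
#' Columns `participant_id`, `task`, `trial`, `rt_s`, `correct` (plus any
#' extras such as `set_size`); tab-separated, UTF-8, `.` decimal.
#'
#' @param table Behaviour tibble.
#' @param path Output TSV path.
#' @return `path` invisibly (write) or the tibble (read).
#' @export
write_behavior <- function(table, path) {
  stopifnot(all(c("participant_id", "task", "trial", "rt_s") %in% names(table)))
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("participant_id", "task", "trial", "rt_s") %in% names(tbl)))
  tbl
}
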