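#' @keywords internal
#' Analytic signal via the frequency-domain construction: zero out negative
#' frequencies, double positive ones. Returns a complex vector whose argument
#' is the instantaneous phase and modulus the instantaneous amplitude.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase FIR band-pass: Hamming-window design with transition width 25%
# of the lower band edge, applied forward-backward so phase is preserved.
fir_bandpass <- function(x, fs, band) {
  stopifnot(band[1] > 0, band[1] < band[2], band[2] < fs / 2)
  trans <- 0.25 * band[1]
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2 == 1) ord <- ord + 1
  ord <- min(ord, max(2L * floor((length(x) - 1) / 6), 10L))
  b <- as.numeric(signal::fir1(ord, band / (fs / 2), type = "pass"))
  signal::filtfilt(b, 1, x)
}

fir_edge_samples <- function(fs, band) {
  trans <- 0.25 * band[1]
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2 == 1) ord <- ord + 1
  ord
}

band_series <- function(recording, channel, band, what = c("phase", "amplitude")) {
  what <- match.arg(what)
  ci <- channel_index(recording, channel)
  filt <- fir_bandpass(recording$signal[ci, ], recording$fs_hz, band)
  z <- analytic_signal(filt)
  if (what == "phase") wrap_phase(Arg(z)) else Mod(z)
}

# Wrap phases to [-pi, pi); the boundary +pi maps to -pi.
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out >= pi] <- -pi
  out
}

#' Band-limited instantaneous phase or amplitude of one channel
#'
#' Zero-phase FIR band-pass filtering of the continuous recording followed by
#' the analytic-signal construction. `bandpass_phase()` returns the
#' instantaneous phase in radians, wrapped to `[-pi, pi)` with 0 at the peak
#' of the band-passed oscillation (cosine convention); `bandpass_amplitude()`
#' returns the non-negative envelope. Samples within one filter length of
#' either boundary are flagged `edge = TRUE` and should be excluded from
#' statistics.
#'
#' @param recording An `eeg_recording`.
#' @param channel Channel name.
#' @param band Length-2 numeric, band edges in Hz; must lie below Nyquist.
#' @return Tibble with columns `time_s`, `phase_rad` or `amplitude`, `edge`.
#' @export
bandpass_phase <- function(recording, channel, band) {
  v <- band_series(recording, channel, band, "phase")
  series_tibble(recording, v, "phase_rad", band)
}

#' @rdname bandpass_phase
#' @export
bandpass_amplitude <- function(recording, channel, band) {
  v <- band_series(recording, channel, band, "amplitude")
  series_tibble(recording, v, "amplitude", band)
}

series_tibble <- function(recording, values, name, band) {
  n <- length(values)
  ne <- min(fir_edge_samples(recording$fs_hz, band), n)
  edge <- rep(FALSE, n)
  edge[seq_len(ne)] <- TRUE
  edge[seq.int(n - ne + 1L, n)] <- TRUE
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1L) / recording$fs_hz,
    !!name := values,
    edge = edge
  )
  out
}

#' Select per-trial analysis windows from trial annotations
#'
#' One half-open interval per trial, from `offset_s` after the prompt to the
#' second click — the span of active selection before the final click becomes
#' sensorimotor routine. Trials whose second click falls at or before the
#' offset end, or that lack the required annotations, are dropped with a
#' warning.
#'
#' @param recording An annotated `eeg_recording`.
#' @param prompt_label,click_labels Annotation labels delimiting the window.
#' @param offset_s Delay after the prompt excluded as sensory processing
#'   (default 0.5 s).
#' @return Tibble of class `analysis_windows` with columns `trial`, `start_s`,
#'   `end_s` plus the trial's click times in `clicks` (list-column).
#' @export
extract_windows <- function(recording, prompt_label = "prompt",
                            click_labels = c("click1", "click2", "click3"),
                            offset_s = 0.5) {
  ann <- recording$annotations
  if (nrow(ann) == 0L) stop("recording has no annotations", call. = FALSE)
  stopifnot("trial" %in% names(ann))
  out <- ann |>
    dplyr::group_by(.data$trial) |>
    dplyr::group_map(function(df, key) {
      prompt <- df$time_s[df$label == prompt_label]
      clicks <- df$time_s[df$label %in% click_labels]
      if (length(prompt) != 1L || length(clicks) < 2L) {
        warning(sprintf("trial %d missing prompt/click annotations; skipped",
                        key$trial), call. = FALSE)
        return(NULL)
      }
      clicks <- sort(clicks)
      start <- prompt + offset_s
      end <- clicks[2]
      if (end <= start) {
        warning(sprintf("trial %d: second click at %.3f s precedes window start; dropped",
                        key$trial, end), call. = FALSE)
        return(NULL)
      }
      tibble::tibble(trial = key$trial, start_s = start, end_s = end,
                     clicks = list(clicks))
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) stop("no usable trials", call. = FALSE)
  class(out) <- c("analysis_windows", class(out))
  out
}

#' Motor masks around click events
#'
#' Marks the +/- `half_width_s` neighbourhood of every click inside each
#' analysis window (400 ms per click at the default), clipped to the window.
#'
#' @param windows An `analysis_windows` tibble carrying click times.
#' @param half_width_s Half-width of each mask in seconds (default 0.2).
#' @return Tibble with columns `trial`, `mask_start_s`, `mask_end_s`.
#' @export
motor_masks <- function(windows, half_width_s = 0.2) {
  stopifnot(inherits(windows, "analysis_windows"))
  purrr::pmap(
    list(windows$trial, windows$start_s, windows$end_s, windows$clicks),
    function(trial, start, end, clicks) {
      ms <- pmax(clicks - half_width_s, start)
      me <- pmin(clicks + half_width_s, end)
      keep <- me > ms
      tibble::tibble(trial = trial, mask_start_s = ms[keep], mask_end_s = me[keep])
    }
  ) |> dplyr::bind_rows()
}

# Sample indices (1-based) covered by half-open interval [start_s, end_s).
window_samples <- function(start_s, end_s, fs) {
  lo <- floor(start_s * fs) + 1L
  hi <- floor(end_s * fs)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Concatenate windowed phase/amplitude samples across trials
#'
#' Phase and amplitude are computed on the continuous recording (so no filter
#' edges appear at joins); this selects the samples inside each analysis
#' window, in trial order, and pastes them into one paired series. With
#' `masks` supplied, `mask_mode = "exclude"` removes the masked (motor)
#' samples, `"only"` keeps only them.
#'
#' @param phase,amplitude Numeric vectors over the full recording (same
#'   length), e.g. the value columns of [bandpass_phase()] /
#'   [bandpass_amplitude()].
#' @param windows An `analysis_windows` tibble.
#' @param fs_hz Sampling rate of the series.
#' @param masks Optional tibble from [motor_masks()].
#' @param mask_mode `"exclude"` or `"only"`.
#' @return Tibble of class `phase_amp_series` with columns `phase_rad`,
#'   `amplitude`.
#' @export
concatenate_windows <- function(phase, amplitude, windows, fs_hz,
                                masks = NULL, mask_mode = c("exclude", "only")) {
  stopifnot(length(phase) == length(amplitude), nrow(windows) > 0L)
  mask_mode <- match.arg(mask_mode)
  idx <- select_window_samples(windows, fs_hz, length(phase), masks, mask_mode)
  if (length(idx) == 0L) stop("no samples selected", call. = FALSE)
  out <- tibble::tibble(phase_rad = wrap_phase(phase[idx]), amplitude = amplitude[idx])
  attr(out, "fs_hz") <- fs_hz
  class(out) <- c("phase_amp_series", class(out))
  out
}

select_window_samples <- function(windows, fs, n_total, masks = NULL,
                                  mask_mode = "exclude") {
  pieces <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- window_samples(windows$start_s[i], windows$end_s[i], fs)
    idx <- idx[idx >= 1L & idx <= n_total]
    if (!is.null(masks)) {
      mk <- masks[masks$trial == windows$trial[i], , drop = FALSE]
      if (nrow(mk) > 0L) {
        masked <- unique(unlist(lapply(seq_len(nrow(mk)), function(j) {
          window_samples(mk$mask_start_s[j], mk$mask_end_s[j], fs)
        })))
        idx <- if (mask_mode == "exclude") setdiff(idx, masked)
               else intersect(idx, masked)
      } else if (mask_mode == "only") {
        idx <- integer(0)
      }
    }
    idx
  })
  unlist(pieces)
}
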