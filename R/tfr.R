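#' Continuous wavelet transform magnitude of a 1-second epoch
#'
#' Time-frequency representation using the generalized Morse wavelet with
#' symmetry parameter `gamma = 3` and time-bandwidth product `P^2 = 60`
#' (so `beta = P^2 / gamma = 20`), evaluated in the frequency domain with a
#' geometric frequency axis (default 12 voices per octave over 2-90 Hz).
#' The Morse wavelet is defined on positive frequencies as
#' `Psi(w) = a * w^beta * exp(-w^gamma)` with `a` chosen so the peak value is
#' 2 (band-pass normalisation); its peak frequency `(beta/gamma)^(1/gamma)`
#' maps scales to Hz.
#'
#' @param x Numeric vector, one epoch of exactly `round(fs_hz)` samples
#'   (1 second).
#' @param fs_hz Sampling rate in Hz.
#' @param gamma Morse symmetry parameter (default 3).
#' @param time_bandwidth Morse time-bandwidth product `P^2` (default 60).
#' @param freq_range Frequency axis limits in Hz (default `c(2, 90)`).
#' @param voices_per_octave Frequency sampling density (default 12).
#' @return A `tfr_map`: list with `freqs_hz`, `times_s`, and the
#'   frequencies-by-times `magnitude` matrix (non-negative).
#' @export
cwt_magnitude <- function(x, fs_hz, gamma = 3, time_bandwidth = 60,
                          freq_range = c(2, 90), voices_per_octave = 12) {
  n <- length(x)
  if (n < round(fs_hz)) stop("epoch shorter than 1 second", call. = FALSE)
  stopifnot(freq_range[1] > 0, freq_range[2] > freq_range[1],
            freq_range[2] <= fs_hz / 2)
  beta <- time_bandwidth / gamma
  wp <- (beta / gamma)^(1 / gamma)          # Morse peak (radian) frequency
  n_oct <- log2(freq_range[2] / freq_range[1])
  freqs <- freq_range[1] * 2^(seq(0, n_oct, by = 1 / voices_per_octave))
  if (max(freqs) < freq_range[2]) freqs <- c(freqs, freq_range[2])
  omega <- 2 * pi * fs_hz * (seq_len(n) - 1L) / n   # rad/s, DFT bins
  omega[omega > pi * fs_hz] <- omega[omega > pi * fs_hz] - 2 * pi * fs_hz
  X <- stats::fft(x)
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    s <- wp / (2 * pi * freqs[k])           # scale mapping peak to freqs[k]
    w <- s * omega
    psi <- numeric(n)
    pos <- w > 0
    psi[pos] <- 2 * exp(beta * log(w[pos]) - w[pos]^gamma -
                          (beta * log(wp) - wp^gamma))
    mag[k, ] <- Mod(stats::fft(X * psi, inverse = TRUE) / n)
  }
  structure(list(freqs_hz = freqs,
                 times_s = (seq_len(n) - 1L) / fs_hz,
                 magnitude = mag),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> %d freqs (%.1f-%.1f Hz) x %d samples\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s)))
  invisible(x)
}

circular_shift_cols <- function(m, k) {
  n <- ncol(m)
  k <- ((k %% n) + n) %% n
  if (k == 0) m else m[, c((n - k + 1L):n, 1L:(n - k)), drop = FALSE]
}

#' Phase-aligned average of epoch time-frequency maps
#'
#' Synchronises epochs before averaging: each epoch's map is circularly
#' shifted along time by `-(phi / (2*pi)) / f_low` seconds, where `phi` is the
#' epoch's reference low-frequency phase — epochs with earlier (more
#' negative) phase move rightward, later ones leftward — so the slow cycle
#' lands at a common position and phase-locked high-frequency amplitude
#' survives averaging. Sub-sample shifts are rounded to the nearest sample;
#' circular shifting preserves each map's energy and the frequency axis.
#'
#' @param maps List of `tfr_map` objects with identical axes.
#' @param phases_rad Numeric vector, reference low-frequency phase of each
#'   epoch (radians) at the epoch midpoint.
#' @param f_low_hz Low (phase-providing) frequency in Hz used for the
#'   phase-to-time conversion.
#' @return A `tfr_map` holding the aligned average.
#' @export
phase_align_average <- function(maps, phases_rad, f_low_hz) {
  stopifnot(length(maps) >= 2L, length(maps) == length(phases_rad), f_low_hz > 0)
  fs <- 1 / diff(maps[[1]]$times_s[1:2])
  dims <- dim(maps[[1]]$magnitude)
  acc <- matrix(0, dims[1], dims[2])
  for (i in seq_along(maps)) {
    if (!identical(dim(maps[[i]]$magnitude), dims)) {
      stop("epoch maps have inconsistent shapes", call. = FALSE)
    }
    shift_s <- -(phases_rad[i] / (2 * pi)) / f_low_hz
    acc <- acc + circular_shift_cols(maps[[i]]$magnitude, round(shift_s * fs))
  }
  structure(list(freqs_hz = maps[[1]]$freqs_hz,
                 times_s = maps[[1]]$times_s,
                 magnitude = acc / length(maps)),
            class = "tfr_map")
}

#' Phase-aligned average TFR over the analysis windows of a recording
#'
#' Tiles each analysis window into non-overlapping 1-second epochs (trailing
#' partial epochs dropped), computes the Morse-wavelet TFR per epoch, reads
#' the theta-band phase at each epoch midpoint from the continuous recording,
#' and returns the phase-aligned average map.
#'
#' @inheritParams mi_within
#' @param phase_band Band (Hz) providing the alignment phase (default theta).
#' @param ... Passed to [cwt_magnitude()].
#' @return A `tfr_map`; the number of epochs used is in attribute `n_epochs`.
#' @export
phase_aligned_tfr <- function(recording, channel, windows,
                              phase_band = c(4, 8), ...) {
  fs <- recording$fs_hz
  ep_len <- round(fs)
  ci <- channel_index(recording, channel)
  x <- recording$signal[ci, ]
  phase <- band_series(recording, channel, phase_band, "phase")
  starts <- unlist(lapply(seq_len(nrow(windows)), function(i) {
    idx <- window_samples(windows$start_s[i], windows$end_s[i], fs)
    if (length(idx) < ep_len) return(integer(0))
    idx[seq.int(1L, length(idx) - ep_len + 1L, by = ep_len)]
  }))
  if (length(starts) < 2L) stop("need at least two full 1-s epochs", call. = FALSE)
  maps <- lapply(starts, function(s0) cwt_magnitude(x[s0:(s0 + ep_len - 1L)], fs, ...))
  phis <- phase[starts + ep_len %/% 2L]
  f_low <- mean(phase_band)
  out <- phase_align_average(maps, phis, f_low)
  attr(out, "n_epochs") <- length(starts)
  out
}

#' Peak-to-trough modulation depth of a frequency band in an averaged TFR
#'
#' Averages magnitude over the rows inside `band` and returns
#' `(max - min) / mean` of the resulting time course — a simple summary of
#' how strongly the band's amplitude waxes and wanes over the aligned slow
#' cycle (near 0 without coupling).
#'
#' @param map A `tfr_map`.
#' @param band Frequency band in Hz (default gamma, 40-80).
#' @return Scalar modulation depth.
#' @export
tfr_modulation_depth <- function(map, band = c(40, 80)) {
  rows <- map$freqs_hz >= band[1] & map$freqs_hz <= band[2]
  stopifnot(any(rows))
  tc <- colMeans(map$magnitude[rows, , drop = FALSE])
  if (mean(tc) == 0) return(0)
  (max(tc) - min(tc)) / mean(tc)
}
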