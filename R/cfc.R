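#' Phase-binned amplitude distribution
#'
#' Discretises the paired series into `n_bins` equal phase bins over
#' `[-pi, pi)` (left-closed, right-open; a phase of exactly `pi` wraps to
#' `-pi`), takes the mean amplitude per bin, and normalises the means to a
#' distribution `p`. Bins receiving no samples get `p = 0` with a warning —
#' that usually signals too few samples for a stable index.
#'
#' @param series A `phase_amp_series` (or any data frame with `phase_rad` and
#'   `amplitude` columns).
#' @param n_bins Number of phase bins (default 18, >= 2).
#' @return A `phase_amp_dist` list: `n_bins`, `bin_edges` (length
#'   `n_bins + 1`), `mean_amp` and `p` per bin, `n_samples`.
#' @export
bin_by_phase <- function(series, n_bins = 18L) {
  stopifnot(n_bins >= 2L, nrow(series) > 0L)
  phi <- wrap_phase(series$phase_rad)
  amp <- series$amplitude
  stopifnot(all(amp >= 0))
  width <- 2 * pi / n_bins
  j <- pmin(floor((phi + pi) / width) + 1L, n_bins)
  counts <- tabulate(j, nbins = n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(amp, j)
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  mean_amp <- ifelse(counts > 0L, sums / counts, 0)
  if (any(counts == 0L)) {
    warning(sprintf("%d of %d phase bins received no samples", sum(counts == 0L), n_bins),
            call. = FALSE)
  }
  tot <- sum(mean_amp)
  if (tot <= 0) stop("degenerate input: all phase bins empty or zero amplitude", call. = FALSE)
  structure(
    list(n_bins = as.integer(n_bins),
         bin_edges = seq(-pi, pi, length.out = n_bins + 1L),
         mean_amp = mean_amp, p = mean_amp / tot,
         n_samples = length(phi)),
    class = "phase_amp_dist"
  )
}

# Normalised KL modulation index from a probability vector (0 log 0 = 0).
mi_from_p <- function(p, n_bins = length(p)) {
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n_bins) - h) / log(n_bins)
}

#' Kullback-Leibler modulation index of a phase-binned distribution
#'
#' `MI = D_KL(P, U) / log(N) = (log N - H(P)) / log N`, the KL divergence of
#' the phase-binned amplitude distribution `P` from the uniform distribution
#' `U`, normalised so MI is 0 for a perfectly uniform distribution (no
#' coupling) and 1 for a point mass (all amplitude in one phase bin). Natural
#' logarithms; the normalisation makes the choice immaterial.
#'
#' @param dist A `phase_amp_dist` from [bin_by_phase()].
#' @return One-row tibble with `mi`, `n_bins`, `n_samples`.
#' @export
modulation_index <- function(dist) {
  stopifnot(inherits(dist, "phase_amp_dist"), dist$n_bins >= 2L)
  tibble::tibble(mi = mi_from_p(dist$p, dist$n_bins),
                 n_bins = dist$n_bins, n_samples = dist$n_samples)
}

# Shared worker: phase from one channel, amplitude from another (possibly the
# same), windows concatenated, binned, MI.
mi_pair <- function(recording, phase_channel, amp_channel, windows,
                    phase_band, amp_band, n_bins, masks, mask_mode) {
  ph <- band_series(recording, phase_channel, phase_band, "phase")
  am <- band_series(recording, amp_channel, amp_band, "amplitude")
  series <- concatenate_windows(ph, am, windows, recording$fs_hz,
                                masks = masks, mask_mode = mask_mode)
  res <- modulation_index(bin_by_phase(series, n_bins))
  tibble::tibble(
    phase_channel = phase_channel, amp_channel = amp_channel,
    phase_low_hz = phase_band[1], phase_high_hz = phase_band[2],
    amp_low_hz = amp_band[1], amp_high_hz = amp_band[2],
    mi = res$mi, n_samples = res$n_samples
  )
}

#' Within-electrode modulation index over analysis windows
#'
#' Theta-band (default 4-8 Hz) phase and gamma-band (default 40-80 Hz)
#' amplitude from the same channel, concatenated over the analysis windows,
#' binned and reduced to the modulation index. Because the binned
#' distribution is normalised, rescaling the raw amplitude leaves MI
#' unchanged.
#'
#' @param recording An `eeg_recording`.
#' @param channel Channel name.
#' @param windows An `analysis_windows` tibble.
#' @param phase_band,amp_band Band edges in Hz.
#' @param n_bins Phase bins (default 18).
#' @param masks,mask_mode Optional motor masks, see [concatenate_windows()].
#' @return One-row tibble with channels, bands, `mi`, `n_samples`.
#' @export
mi_within <- function(recording, channel, windows,
                      phase_band = c(4, 8), amp_band = c(40, 80),
                      n_bins = 18L, masks = NULL, mask_mode = "exclude") {
  mi_pair(recording, channel, channel, windows, phase_band, amp_band,
          n_bins, masks, mask_mode)
}

#' Cross-electrode modulation index (phase at A, amplitude at B)
#'
#' The directed coupling A -> B: how strongly the low-frequency phase at
#' `phase_channel` organises the high-frequency amplitude at `amp_channel`.
#' With identical channels this reduces to [mi_within()].
#'
#' @inheritParams mi_within
#' @param phase_channel,amp_channel Source (phase) and target (amplitude)
#'   channel names.
#' @return One-row tibble with channels, bands, `mi`, `n_samples`.
#' @export
mi_cross <- function(recording, phase_channel, amp_channel, windows,
                     phase_band = c(4, 8), amp_band = c(40, 80),
                     n_bins = 18L, masks = NULL, mask_mode = "exclude") {
  mi_pair(recording, phase_channel, amp_channel, windows, phase_band, amp_band,
          n_bins, masks, mask_mode)
}

#' Segment-wise time-binned MI indicators
#'
#' Splits a concatenated phase/amplitude series into `segment_count`
#' contiguous, equal-length segments (by samples). Within each segment the
#' series is cut into consecutive `bin_s`-second bins, a partial final bin is
#' discarded, MI is computed per full bin and averaged. The per-segment means
#' serve as neural indicators for the factor models; a segment with no full
#' bin yields `NA` with a warning.
#'
#' @param series A `phase_amp_series`.
#' @param segment_count Number of segments (default 3).
#' @param bin_s Bin length in seconds (default 5).
#' @param n_bins Phase bins per MI computation.
#' @return Tibble with one row per segment: `segment`, `n_time_bins`, `mi`.
#' @export
mi_time_binned <- function(series, segment_count = 3L, bin_s = 5, n_bins = 18L) {
  fs <- attr(series, "fs_hz")
  stopifnot(!is.null(fs), segment_count >= 1L, bin_s > 0)
  n <- nrow(series)
  seg_len <- n %/% segment_count
  if (seg_len == 0L) stop("series shorter than segment count", call. = FALSE)
  bin_len <- floor(bin_s * fs)
  purrr::map(seq_len(segment_count), function(s) {
    lo <- (s - 1L) * seg_len + 1L
    seg <- series[seq.int(lo, lo + seg_len - 1L), ]
    k <- nrow(seg) %/% bin_len
    if (k == 0L) {
      warning(sprintf("segment %d has no full %g-s bin; indicator undefined", s, bin_s),
              call. = FALSE)
      return(tibble::tibble(segment = s, n_time_bins = 0L, mi = NA_real_))
    }
    mis <- vapply(seq_len(k), function(b) {
      idx <- seq.int((b - 1L) * bin_len + 1L, b * bin_len)
      mi_from_p(bin_by_phase(seg[idx, ], n_bins)$p)
    }, numeric(1))
    tibble::tibble(segment = s, n_time_bins = k, mi = mean(mis))
  }) |> dplyr::bind_rows()
}

#' Modulation index over a grid of phase/amplitude frequency bands
#'
#' Recomputes MI for every combination of narrow phase bands (default 3-10 Hz
#' in 1-Hz steps) and amplitude bands (default 30-80 Hz in 10-Hz steps) on
#' one channel — the per-participant comodulogram. Significance against a
#' permutation null is a group-level operation: see
#' [comodulogram_significance()].
#'
#' @inheritParams mi_within
#' @param phase_edges,amp_edges Increasing vectors of band edges in Hz;
#'   consecutive pairs form the bands.
#' @return Tibble of class `comodulogram` with one row per grid cell:
#'   `phase_low_hz`, `phase_high_hz`, `amp_low_hz`, `amp_high_hz`, `mi`.
#' @export
comodulogram <- function(recording, channel, windows,
                         phase_edges = 3:10, amp_edges = seq(30, 80, by = 10),
                         n_bins = 18L, masks = NULL, mask_mode = "exclude") {
  fs <- recording$fs_hz
  stopifnot(max(amp_edges) < fs / 2, length(phase_edges) >= 2, length(amp_edges) >= 2)
  idx <- select_window_samples(windows, fs, ncol(recording$signal), masks, mask_mode)
  ci <- channel_index(recording, channel)
  x <- recording$signal[ci, ]

  phase_bands <- purrr::map(seq_len(length(phase_edges) - 1L),
                            ~ c(phase_edges[.x], phase_edges[.x + 1L]))
  amp_bands <- purrr::map(seq_len(length(amp_edges) - 1L),
                          ~ c(amp_edges[.x], amp_edges[.x + 1L]))
  phases <- purrr::map(phase_bands,
                       ~ wrap_phase(Arg(analytic_signal(fir_bandpass(x, fs, .x))))[idx])
  amps <- purrr::map(amp_bands,
                     ~ Mod(analytic_signal(fir_bandpass(x, fs, .x)))[idx])

  grid <- tidyr::expand_grid(pi_ = seq_along(phase_bands), ai_ = seq_along(amp_bands))
  out <- purrr::pmap(grid, function(pi_, ai_) {
    s <- tibble::tibble(phase_rad = phases[[pi_]], amplitude = amps[[ai_]])
    tibble::tibble(
      phase_low_hz = phase_bands[[pi_]][1], phase_high_hz = phase_bands[[pi_]][2],
      amp_low_hz = amp_bands[[ai_]][1], amp_high_hz = amp_bands[[ai_]][2],
      mi = mi_from_p(bin_by_phase(s, n_bins)$p)
    )
  }) |> dplyr::bind_rows()
  attr(out, "channel") <- channel
  class(out) <- c("comodulogram", class(out))
  out
}

#' Group comodulogram significance against a permutation null
#'
#' Averages per-participant comodulograms cell-wise, then builds a null by
#' shuffling each participant's MI values uniformly across the
#' phase-amplitude frequency matrix `n_perm` times and re-averaging. A cell
#' is flagged significant when its group-average MI exceeds the null mean
#' plus `sd_mult` null standard deviations. Under no coupling all cells are
#' exchangeable, so the mask stays essentially empty.
#'
#' @param comods List of `comodulogram` tibbles on a common grid (a single
#'   comodulogram is treated as a group of one).
#' @param n_perm Number of permutations (default 1000; fewer than 100 draws a
#'   warning).
#' @param sd_mult Threshold in null SDs above the null mean (default 3).
#' @param seed Integer seed for the permutations.
#' @return Tibble of class `comodulogram_group`: grid columns, `mi`
#'   (group mean), `significant`, with `null_mean`, `null_sd`, `threshold`
#'   attributes.
#' @export
comodulogram_significance <- function(comods, n_perm = 1000L, sd_mult = 3,
                                      seed = 1L) {
  if (inherits(comods, "comodulogram")) comods <- list(comods)
  stopifnot(length(comods) >= 1L)
  if (n_perm < 100L) warning("n_perm < 100 gives an unstable null", call. = FALSE)
  grid <- comods[[1]][c("phase_low_hz", "phase_high_hz", "amp_low_hz", "amp_high_hz")]
  mi_mat <- vapply(comods, function(cm) {
    stopifnot(nrow(cm) == nrow(grid))
    cm$mi
  }, numeric(nrow(grid)))
  mi_mat <- matrix(mi_mat, nrow = nrow(grid))
  group_mean <- rowMeans(mi_mat)
  n_cells <- nrow(grid)
  null_vals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      perm <- vapply(seq_len(ncol(mi_mat)),
                     function(p) mi_mat[sample.int(n_cells), p],
                     numeric(n_cells))
      rowMeans(matrix(perm, nrow = n_cells))
    }, numeric(n_cells))
  })
  null_mean <- mean(null_vals)
  null_sd <- stats::sd(as.vector(null_vals))
  thr <- null_mean + sd_mult * null_sd
  out <- tibble::as_tibble(grid)
  out$mi <- group_mean
  out$significant <- group_mean > thr
  attr(out, "null_mean") <- null_mean
  attr(out, "null_sd") <- null_sd
  attr(out, "threshold") <- thr
  attr(out, "n_perm") <- as.integer(n_perm)
  class(out) <- c("comodulogram_group", class(out))
  out
}

#' Motor versus non-motor modulation index within the analysis window
#'
#' Splits each participant's analysis-window samples into motor epochs
#' (within +/- 200 ms of a click by default) and the complementary non-motor
#' samples, and computes MI on each subset. The two masks partition the
#' window, so their sample counts sum to the full window length.
#'
#' @inheritParams mi_within
#' @param half_width_s Motor-mask half width in seconds (default 0.2).
#' @return One-row tibble: `mi_motor`, `mi_nonmotor`, `n_motor`, `n_nonmotor`.
#' @export
mi_motor_contrast <- function(recording, channel, windows,
                              phase_band = c(4, 8), amp_band = c(40, 80),
                              n_bins = 18L, half_width_s = 0.2) {
  masks <- motor_masks(windows, half_width_s)
  motor <- mi_within(recording, channel, windows, phase_band, amp_band,
                     n_bins, masks = masks, mask_mode = "only")
  nonmotor <- mi_within(recording, channel, windows, phase_band, amp_band,
                        n_bins, masks = masks, mask_mode = "exclude")
  tibble::tibble(mi_motor = motor$mi, mi_nonmotor = nonmotor$mi,
                 n_motor = motor$n_samples, n_nonmotor = nonmotor$n_samples)
}

#' Group-level paired test of motor versus non-motor MI
#'
#' Paired t-test across participants of the motor minus non-motor MI
#' difference; non-significance indicates the coupling estimate is not
#' dominated by click-locked motor activity.
#'
#' @param contrasts Tibble with one row per participant, columns `mi_motor`
#'   and `mi_nonmotor` (e.g. stacked [mi_motor_contrast()] rows).
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p_value`, `conf_low`,
#'   `conf_high`.
#' @export
motor_contrast_test <- function(contrasts) {
  stopifnot(nrow(contrasts) >= 2L)
  tt <- stats::t.test(contrasts$mi_motor, contrasts$mi_nonmotor, paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
}

#' Scalar CFC strength over the central-parietal cluster
#'
#' Mean within-electrode MI over CP1, CP2, Pz and Cz — the conventional
#' scalar summary when one "CFC strength" per participant is needed.
#'
#' @inheritParams mi_within
#' @param channels Channels to average (default the central-parietal four).
#' @return One-row tibble with `cfc_strength` and the per-channel MIs nested
#'   in `per_channel`.
#' @export
cfc_strength <- function(recording, windows,
                         channels = c("CP1", "CP2", "Pz", "Cz"),
                         phase_band = c(4, 8), amp_band = c(40, 80),
                         n_bins = 18L) {
  per <- purrr::map(channels, ~ mi_within(recording, .x, windows,
                                          phase_band, amp_band, n_bins)) |>
    dplyr::bind_rows()
  tibble::tibble(cfc_strength = mean(per$mi), per_channel = list(per))
}
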