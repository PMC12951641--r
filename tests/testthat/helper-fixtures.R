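# Shared small fixtures, built once per test run.

# Single-channel recording with a planted 6 -> 60 Hz coupling and annotated
# trials; cheap enough to reuse across files.
fixture_coupled_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cp <- coupling_spec("Cz", "Cz", phase_freq_hz = 6, amp_freq_hz = 60,
                          strength_chi = 0.9)
      r <- generate_recording(c("Cz"), 60, 250, list(cp), seed = 1)
      cache <<- generate_events(r, 4, seed = 2)
    }
    cache
  }
})

fixture_windows <- function() extract_windows(fixture_coupled_recording())

# Independently coded brute-force MI: per-sample binning loop, running sums,
# direct entropy. Deliberately naive and separate from the package path.
oracle_mi <- function(phase, amplitude, n_bins = 18L) {
  width <- 2 * pi / n_bins
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (i in seq_along(phase)) {
    ph <- phase[i]
    while (ph < -pi) ph <- ph + 2 * pi
    while (ph >= pi) ph <- ph - 2 * pi
    j <- floor((ph + pi) / width) + 1L
    if (j > n_bins) j <- n_bins
    sums[j] <- sums[j] + amplitude[i]
    counts[j] <- counts[j] + 1L
  }
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) if (counts[j] > 0L) means[j] <- sums[j] / counts[j]
  p <- means / sum(means)
  H <- 0
  for (j in seq_len(n_bins)) if (p[j] > 0) H <- H - p[j] * log(p[j])
  (log(n_bins) - H) / log(n_bins)
}

# Small 8-channel sub-montage used wherever a full 32-channel run would only
# add filter time.
montage_8 <- c("FT9", "FC5", "FC1", "Cz", "C3", "CP1", "Pz", "Oz")

# Null MI matrix for a participant: i.i.d. noise entries, so the
# directionality contrast of every pair is exchangeable around zero.
null_mi_matrix <- function(channels = montage_8) {
  m <- tidyr::expand_grid(phase_channel = channels, amp_channel = channels)
  m$mi <- stats::runif(length(channels)^2, 0, 0.02)
  attr(m, "channels") <- channels
  class(m) <- c("mi_matrix", class(m))
  m
}

wm_factor_spec <- list(MT = paste0("maintenance_p", 1:4),
                       MP = paste0("manipulation_p", 1:4))
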