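#' Specify one planted phase-amplitude coupling
#'
#' Describes ground-truth coupling for the synthetic EEG generator: the phase
#' of a low-frequency oscillation on `source_channel` modulates the amplitude
#' of a high-frequency carrier on `target_channel`. With modulation depth
#' `strength_chi` = 0 the carrier envelope is flat (no coupling); at 1 the
#' envelope swings between 0 and 1 over the slow cycle.
#'
#' @param source_channel,target_channel Channel names within the montage; may
#'   be identical for within-electrode coupling.
#' @param phase_freq_hz Slow (phase-providing) frequency, Hz, in `[3, 10]`.
#' @param amp_freq_hz Fast (amplitude-providing) carrier frequency, Hz, in
#'   `[30, 80]`.
#' @param strength_chi Modulation depth in `[0, 1]`.
#' @param preferred_phase_rad Slow phase (radians, cosine convention) at which
#'   the fast envelope peaks.
#' @param noise_sd SD of additional Gaussian noise added to the target
#'   channel on top of the recording-wide background noise.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(source_channel, target_channel,
                          phase_freq_hz = 6, amp_freq_hz = 60,
                          strength_chi = 0.8, preferred_phase_rad = 0,
                          noise_sd = 0) {
  stopifnot(
    strength_chi >= 0, strength_chi <= 1,
    phase_freq_hz >= 3, phase_freq_hz <= 10,
    amp_freq_hz >= 30, amp_freq_hz <= 80,
    phase_freq_hz < amp_freq_hz,
    noise_sd >= 0,
    preferred_phase_rad >= -pi, preferred_phase_rad < pi
  )
  structure(
    list(source_channel = source_channel, target_channel = target_channel,
         phase_freq_hz = phase_freq_hz, amp_freq_hz = amp_freq_hz,
         strength_chi = strength_chi,
         preferred_phase_rad = preferred_phase_rad, noise_sd = noise_sd),
    class = "coupling_spec"
  )
}

#' Generate a synthetic EEG-like recording with known coupling
#'
#' Every channel receives Gaussian white background noise. For each coupling,
#' the source channel additionally carries a slow oscillation
#' `cos(theta(t))` with `theta(t) = 2*pi*f_p*t + phi0`, and the target channel
#' carries a fast carrier whose envelope is
#' `(1 + strength_chi * cos(theta(t) - preferred_phase_rad)) / 2`,
#' the standard amplitude-modulation construction for simulated
#' phase-amplitude coupling: the modulation index decays continuously to the
#' noise floor as `strength_chi` goes to 0. The slow oscillation's starting
#' phase is drawn once per coupling so repeated participants differ.
#'
#' @param montage Character vector of channel names (default the built-in
#'   32-channel 10-20 montage).
#' @param duration_s Recording length in seconds.
#' @param fs_hz Sampling rate; must be at least 4x the fastest carrier.
#' @param couplings List of [coupling_spec()] objects (possibly empty).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   recordings. The global RNG state is left untouched.
#' @param background_sd SD of the white background noise on every channel.
#' @param slow_amplitude,carrier_amplitude Peak amplitudes (uV) of the slow
#'   oscillation and the fast carrier.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(montage = montage_32, duration_s, fs_hz,
                               couplings = list(), seed,
                               background_sd = 1,
                               slow_amplitude = 1, carrier_amplitude = 1) {
  stopifnot(duration_s > 0, fs_hz > 0)
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  for (cp in couplings) {
    if (!all(c(cp$source_channel, cp$target_channel) %in% montage)) {
      stop("coupling channels must exist in the montage", call. = FALSE)
    }
    if (fs_hz < 4 * cp$amp_freq_hz) {
      stop(sprintf("fs_hz = %g below 4x the amplitude carrier (%g Hz)",
                   fs_hz, cp$amp_freq_hz), call. = FALSE)
    }
  }
  n <- floor(duration_s * fs_hz)
  t <- (seq_len(n) - 1L) / fs_hz
  withr::with_seed(as.integer(seed), {
    sig <- matrix(stats::rnorm(length(montage) * n, sd = background_sd),
                  nrow = length(montage))
    for (cp in couplings) {
      src <- match(cp$source_channel, montage)
      tgt <- match(cp$target_channel, montage)
      phi0 <- stats::runif(1, -pi, pi)
      theta <- 2 * pi * cp$phase_freq_hz * t + phi0
      xi <- stats::runif(1, -pi, pi)
      envelope <- (1 + cp$strength_chi * cos(theta - cp$preferred_phase_rad)) / 2
      sig[src, ] <- sig[src, ] + slow_amplitude * cos(theta)
      sig[tgt, ] <- sig[tgt, ] +
        carrier_amplitude * envelope * cos(2 * pi * cp$amp_freq_hz * t + xi)
      if (cp$noise_sd > 0) {
        sig[tgt, ] <- sig[tgt, ] + stats::rnorm(n, sd = cp$noise_sd)
      }
    }
    new_recording(sig, fs_hz, montage)
  })
}

#' Default trial timeline for the simulated selection task
#'
#' Three sample images (1 s each, 1.5 s inter-stimulus interval), a 1-s
#' sequence prompt, then three mouse clicks whose latencies are drawn from
#' lognormal distributions, feedback and an inter-trial gap. Click latency
#' parameters are on the log scale.
#'
#' @param image_dur_s,isi_s,prompt_dur_s,feedback_s,iti_s Timeline segment
#'   durations in seconds.
#' @param click1_meanlog,click_gap_meanlog,click_sdlog Lognormal parameters of
#'   the prompt-to-first-click latency and the between-click gaps.
#' @return A `trial_layout` list consumed by [generate_events()].
#' @export
trial_layout <- function(image_dur_s = 1, isi_s = 1.5, prompt_dur_s = 1,
                         feedback_s = 1, iti_s = 1,
                         click1_meanlog = log(1.2), click_gap_meanlog = log(1.0),
                         click_sdlog = 0.25) {
  structure(as.list(environment()), class = "trial_layout")
}

#' Annotate a recording with simulated trial events
#'
#' Appends per-trial annotations (three image onsets, the prompt onset, three
#' click times) laid out back-to-back from time 0. Event times are strictly
#' increasing within each trial.
#'
#' @param recording An `eeg_recording`.
#' @param n_trials Number of trials to place (0 gives an empty annotation set).
#' @param layout A [trial_layout()].
#' @param seed Integer seed for the click-latency draws.
#' @return The recording with its `annotations` tibble populated.
#' @export
generate_events <- function(recording, n_trials, layout = trial_layout(), seed) {
  stopifnot(inherits(recording, "eeg_recording"), n_trials >= 0)
  if (n_trials == 0L) {
    recording$annotations <- empty_annotations()
    return(recording)
  }
  lay <- layout
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_trials)
    t0 <- 0
    for (tr in seq_len(n_trials)) {
      img <- t0 + (0:2) * (lay$image_dur_s + lay$isi_s)
      prompt <- img[3] + lay$image_dur_s + lay$isi_s
      click1 <- prompt + lay$prompt_dur_s +
        stats::rlnorm(1, lay$click1_meanlog, lay$click_sdlog)
      click2 <- click1 + stats::rlnorm(1, lay$click_gap_meanlog, lay$click_sdlog)
      click3 <- click2 + stats::rlnorm(1, lay$click_gap_meanlog, lay$click_sdlog)
      rows[[tr]] <- tibble::tibble(
        label = c("image1", "image2", "image3", "prompt",
                  "click1", "click2", "click3"),
        time_s = c(img, prompt, click1, click2, click3),
        trial = tr
      )
      t0 <- click3 + lay$feedback_s + lay$iti_s
    }
    ann <- dplyr::bind_rows(rows)
    if (max(ann$time_s) > duration_s(recording)) {
      stop(sprintf("trials overflow recording length (%.1f s needed, %.1f s available)",
                   max(ann$time_s), duration_s(recording)), call. = FALSE)
    }
    recording$annotations <- ann
    recording
  })
}
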