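mk_series <- function(phase, amplitude, fs = 250) {
  out <- tibble::tibble(phase_rad = phase, amplitude = amplitude)
  attr(out, "fs_hz") <- fs
  class(out) <- c("phase_amp_series", class(out))
  out
}

test_that("phase binning matches analytic cases and the brute-force oracle", {
  # uniform phases, constant amplitude -> p = 1/18 in every bin
  n <- 18 * 50
  phase <- seq(-pi, pi - 1e-9, length.out = n)
  d <- bin_by_phase(mk_series(phase, rep(1, n)))
  expect_equal(d$p, rep(1 / 18, 18), tolerance = 1e-12)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)

  # amplitude confined to one bin -> point mass there
  amp <- as.numeric(phase >= d$bin_edges[5] & phase < d$bin_edges[6])
  d5 <- suppressWarnings(bin_by_phase(mk_series(phase, amp)))
  expect_equal(d5$p[5], 1)
  expect_equal(sum(d5$p[-5]), 0)

  # random samples agree with the independent per-sample loop to 1e-12
  withr::with_seed(8, {
    for (rep in 1:5) {
      ph <- stats::runif(1000, -pi, pi)
      am <- stats::rexp(1000)
      d <- bin_by_phase(mk_series(ph, am))
      expect_equal(thetagamma:::mi_from_p(d$p), oracle_mi(ph, am),
                   tolerance = 1e-12)
    }
  })
})

test_that("modulation index attains its analytic limits and frozen oracle value", {
  mk_dist <- function(p) {
    structure(list(n_bins = length(p),
                   bin_edges = seq(-pi, pi, length.out = length(p) + 1L),
                   mean_amp = p, p = p, n_samples = 1000L),
              class = "phase_amp_dist")
  }
  expect_equal(modulation_index(mk_dist(rep(1 / 18, 18)))$mi, 0)
  expect_equal(modulation_index(mk_dist(c(1, rep(0, 17))))$mi, 1)
  # p proportional to exp(cos(theta_j)) over the 18 bin centres: value frozen
  # from a direct independent entropy evaluation
  centers <- -pi + (2 * pi / 18) * (0:17 + 0.5)
  p <- exp(cos(centers)); p <- p / sum(p)
  expect_equal(modulation_index(mk_dist(p))$mi, 0.072819562678870,
               tolerance = 1e-12)
})

test_that("MI is invariant under amplitude rescaling", {
  withr::with_seed(13, {
    ph <- stats::runif(3000, -pi, pi)
    am <- stats::rexp(3000)
  })
  mi1 <- thetagamma:::mi_from_p(bin_by_phase(mk_series(ph, am))$p)
  mi2 <- thetagamma:::mi_from_p(bin_by_phase(mk_series(ph, 37.5 * am))$p)
  expect_equal(mi1, mi2, tolerance = 1e-12)
})

test_that("windowed MI is deterministic and band-specific", {
  rec <- fixture_coupled_recording()
  w <- fixture_windows()
  a <- mi_within(rec, "Cz", w)
  b <- mi_within(rec, "Cz", w)
  expect_identical(a, b)
  # coupling planted at 6 -> 60 Hz: the matched bands beat off-bands
  off <- mi_within(rec, "Cz", w, phase_band = c(8, 9), amp_band = c(30, 40))
  expect_gt(a$mi, off$mi)
})

test_that("cross-electrode MI with identical channels equals within-electrode MI", {
  rec <- fixture_coupled_recording()
  w <- fixture_windows()
  expect_equal(mi_cross(rec, "Cz", "Cz", w)$mi, mi_within(rec, "Cz", w)$mi)
})

test_that("time-binned indicators follow the 5-second binning rules", {
  fs <- 250
  withr::with_seed(3, {
    s <- mk_series(stats::runif(30 * fs, -pi, pi), stats::rexp(30 * fs), fs)
  })
  out <- mi_time_binned(s, segment_count = 3L, bin_s = 5)
  expect_equal(out$segment, 1:3)
  expect_equal(out$n_time_bins, rep(2L, 3))   # 10 s per segment -> 2 full bins

  # 12-s segment: bins [0,5), [5,10), trailing 2 s discarded
  withr::with_seed(4, {
    s12 <- mk_series(stats::runif(12 * fs, -pi, pi), stats::rexp(12 * fs), fs)
  })
  one <- mi_time_binned(s12, segment_count = 1L, bin_s = 5)
  expect_equal(one$n_time_bins, 2L)
  # and the mean matches recomputing the two bins by hand
  b1 <- thetagamma:::mi_from_p(bin_by_phase(s12[1:(5 * fs), ])$p)
  b2 <- thetagamma:::mi_from_p(bin_by_phase(s12[(5 * fs + 1):(10 * fs), ])$p)
  expect_equal(one$mi, mean(c(b1, b2)))

  # segment too short for any full bin -> NA with a warning
  withr::with_seed(5, {
    tiny <- mk_series(stats::runif(9 * fs, -pi, pi), stats::rexp(9 * fs), fs)
  })
  expect_warning(und <- mi_time_binned(tiny, segment_count = 3L, bin_s = 5),
                 "no full")
  expect_true(all(is.na(und$mi)))
})

test_that("time-binned indicators are mutually consistent across participants", {
  # participants with heterogeneous stationary coupling: all three segment
  # indicators measure the same underlying strength, so they co-vary
  inds <- purrr::map(1:14, function(i) {
    chi <- 0.1 + 0.8 * (i - 1) / 13
    cp <- coupling_spec("Cz", "Cz", strength_chi = chi)
    r <- generate_recording(c("Cz"), 130, 250, list(cp), seed = 800 + i)
    r <- generate_events(r, 9, seed = 850 + i)
    w <- extract_windows(r)
    ph <- thetagamma:::band_series(r, "Cz", c(4, 8), "phase")
    am <- thetagamma:::band_series(r, "Cz", c(40, 80), "amplitude")
    s <- concatenate_windows(ph, am, w, r$fs_hz)
    mi_time_binned(s, segment_count = 3L, bin_s = 5)$mi
  })
  M <- do.call(rbind, inds)
  cors <- stats::cor(M)[upper.tri(diag(3))]
  expect_true(all(cors > 0.5))
})

test_that("comodulogram grid has the stated shape and localizes planted coupling", {
  rec <- fixture_coupled_recording()
  w <- fixture_windows()
  cm <- comodulogram(rec, "Cz", w)
  expect_equal(nrow(cm), 7L * 5L)
  expect_equal(unique(cm$phase_high_hz - cm$phase_low_hz), 1)
  expect_equal(unique(cm$amp_high_hz - cm$amp_low_hz), 10)
  top <- cm[which.max(cm$mi), ]
  expect_true(top$phase_low_hz %in% 5:6)
  expect_true(top$amp_low_hz %in% c(50, 60))
})

test_that("comodulogram significance is deterministic in its seed", {
  rec <- fixture_coupled_recording()
  cm <- comodulogram(rec, "Cz", fixture_windows())
  g1 <- comodulogram_significance(cm, n_perm = 200, seed = 6)
  g2 <- comodulogram_significance(cm, n_perm = 200, seed = 6)
  expect_identical(g1$significant, g2$significant)
  expect_warning(comodulogram_significance(cm, n_perm = 50, seed = 1), "unstable")
})

test_that("motor and non-motor masks partition the analysis window", {
  rec <- fixture_coupled_recording()
  w <- fixture_windows()
  ct <- mi_motor_contrast(rec, "Cz", w)
  full <- mi_within(rec, "Cz", w)
  expect_equal(ct$n_motor + ct$n_nonmotor, full$n_samples)
  # windows entirely inside the motor mask leave no non-motor samples
  w1 <- tibble::tibble(trial = 1L, start_s = 10, end_s = 10.3,
                       clicks = list(c(10.1, 10.2)))
  class(w1) <- c("analysis_windows", class(w1))
  expect_error(mi_motor_contrast(rec, "Cz", w1), "no samples")
})

test_that("group motor-contrast test reports a paired t", {
  withr::with_seed(31, {
    ct <- tibble::tibble(mi_motor = stats::runif(10, 0, 0.01),
                         mi_nonmotor = stats::runif(10, 0, 0.01))
  })
  res <- motor_contrast_test(ct)
  ref <- stats::t.test(ct$mi_motor, ct$mi_nonmotor, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})
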