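test_that("pair enumeration covers all unordered montage pairs", {
  p8 <- channel_pairs(montage_8)
  expect_equal(nrow(p8), choose(8, 2))
  expect_true(all(match(p8$chan_a, montage_8) < match(p8$chan_b, montage_8)))
  expect_equal(nrow(channel_pairs(montage_32)), 496L)
})

test_that("the MI matrix covers every ordered pair and recovers a planted edge", {
  cp <- coupling_spec("FT9", "Cz", strength_chi = 0.8)
  r <- generate_recording(montage_8, 60, 250, list(cp), seed = 2)
  r <- generate_events(r, 4, seed = 12)
  M <- mi_matrix(r, extract_windows(r))
  expect_equal(nrow(M), 64L)
  expect_true(all(M$mi >= 0 & M$mi <= 1))
  off <- M[M$phase_channel != M$amp_channel, ]
  top <- off[which.max(off$mi), ]
  expect_equal(top$phase_channel, "FT9")
  expect_equal(top$amp_channel, "Cz")
})

test_that("Holm adjustment matches the reference implementation and its bounds", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      p <- stats::runif(25)^2
      ours <- holm_adjust(p)
      expect_equal(ours, stats::p.adjust(p, method = "holm"), tolerance = 1e-15)
      bonf <- pmin(p * length(p), 1)
      alpha <- 0.05
      # Bonferroni rejections form a subset of Holm's, Holm's of unadjusted
      expect_true(all(which(bonf <= alpha) %in% which(ours <= alpha)))
      expect_true(all(which(ours <= alpha) %in% which(p <= alpha)))
    }
  })
  # NA passthrough
  p <- c(0.01, NA, 0.5)
  a <- holm_adjust(p)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], stats::p.adjust(p[c(1, 3)], "holm"))
})

test_that("directionality contrast is antisymmetric and needs a cohort", {
  withr::with_seed(20, mats <- lapply(1:5, function(i) null_mi_matrix()))
  d <- directionality(mats)
  # recompute dMI for the reversed pair ordering: must be the negation
  m1 <- matrix(mats[[1]]$mi, 8, byrow = TRUE,
               dimnames = list(montage_8, montage_8))
  for (k in c(1, 7, 20)) {
    a <- d$chan_a[k]; b <- d$chan_b[k]
    dk <- attr(d, "dmi")[k, 1]
    expect_equal(dk, m1[a, b] - m1[b, a])
    expect_equal(-(m1[b, a] - m1[a, b]), dk)
  }
  expect_equal(nrow(d), choose(8, 2))
  expect_error(directionality(mats[1:2]))
})

test_that("a planted asymmetry is recovered as a directed edge", {
  withr::with_seed(33, {
    mats <- lapply(1:10, function(i) {
      m <- null_mi_matrix()
      m$mi[m$phase_channel == "FT9" & m$amp_channel == "Cz"] <-
        0.05 + stats::runif(1, 0, 0.01)
      m
    })
  })
  e <- network_edges(directionality(mats))
  expect_true(any(e$source == "FT9" & e$target == "Cz"))
  expect_false(any(e$source == "Cz" & e$target == "FT9"))
})

test_that("zero-variance pairs are flagged rather than tested", {
  m0 <- null_mi_matrix()
  m0$mi <- rep(0.01, 64)
  expect_warning(d <- directionality(list(m0, m0, m0)), "zero variance")
  expect_true(all(is.na(d$p_adj)))
  expect_false(any(d$significant))
})

test_that("task contrast on identical conditions finds nothing and exclusivity works", {
  withr::with_seed(44, mats <- lapply(1:6, function(i) null_mi_matrix()))
  suppressWarnings(tc <- task_contrast(mats, mats))
  expect_false(any(tc$contrast$significant, na.rm = TRUE))
  expect_equal(nrow(tc$exclusive_task1), 0L)
  expect_equal(nrow(tc$exclusive_task2), 0L)

  # a strong plant only in task 2 appears in task 2's exclusive set
  withr::with_seed(45, {
    t1 <- lapply(1:10, function(i) null_mi_matrix())
    t2 <- lapply(1:10, function(i) {
      m <- null_mi_matrix()
      m$mi[m$phase_channel == "Pz" & m$amp_channel == "Cz"] <-
        0.06 + stats::runif(1, 0, 0.01)
      m
    })
  })
  tc2 <- task_contrast(t1, t2)
  expect_true(any(tc2$exclusive_task2$source == "Pz" &
                    tc2$exclusive_task2$target == "Cz"))
  expect_false(any(tc2$exclusive_task1$source == "Pz" &
                     tc2$exclusive_task1$target == "Cz"))
})

test_that("strongest modulators rank planted sources with deterministic ties", {
  withr::with_seed(55, {
    mats <- lapply(1:8, function(i) {
      m <- null_mi_matrix()
      for (src in c("FT9", "FC5", "Pz")) {
        m$mi[m$phase_channel == src & m$amp_channel == "Cz"] <-
          0.05 + stats::runif(1, 0, 0.005)
      }
      m
    })
  })
  top <- strongest_modulators(mats, "Cz", k = 3)
  expect_setequal(top$source, c("FT9", "FC5", "Pz"))
  expect_equal(nrow(strongest_modulators(mats, "Cz", k = 0)), 0L)

  # exact ties resolve by montage order
  m <- null_mi_matrix()
  m$mi <- rep(0.01, 64)
  tie <- strongest_modulators(list(m), "Cz", k = 2)
  expect_equal(tie$source, c("FT9", "FC5"))
})

test_that("family-wise error stays controlled on null cohorts", {
  # 200 fast null cohorts at the matrix level (the full 500-replicate run
  # backs the acceptance suite)
  withr::with_seed(66, {
    any_hit <- vapply(1:200, function(i) {
      mats <- lapply(1:8, function(j) null_mi_matrix())
      any(directionality(mats)$significant)
    }, logical(1))
  })
  fwer <- mean(any_hit)
  expect_lte(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})
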