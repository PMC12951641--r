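test_that("indicators are medians over trial-order partitions", {
  tbl <- tibble::tibble(
    participant_id = "P1", task = "maintenance", trial = 1:40,
    rt_s = c(rep(1, 10), rep(2, 10), rep(3, 10), c(1, 2, 100, rep(2, 7))),
    correct = TRUE
  )
  ind <- make_indicators(tbl)
  expect_equal(ind$maintenance_p1, 1)
  expect_equal(ind$maintenance_p2, 2)
  expect_equal(ind$maintenance_p3, 3)
  expect_equal(ind$maintenance_p4, 2)   # median shrugs off the 100-s lapse
})

test_that("span tasks are partitioned by set size", {
  tbl <- tibble::tibble(
    participant_id = rep("P1", 15), task = "ospan", trial = 1:15,
    rt_s = rep(3:7, each = 3) + rep(c(-0.1, 0, 0.1), 5),
    correct = TRUE, set_size = rep(3:7, each = 3)
  )
  ind <- make_indicators(tbl)
  expect_equal(sort(names(ind)[-1]), sort(paste0("ospan_s", 3:7)))
  expect_equal(ind$ospan_s5, 5)
})

test_that("participants missing a partition are dropped with a warning", {
  full <- generate_behavior(3, seed = 2)
  partial <- dplyr::filter(full, !(.data$participant_id == "P002" &
                                     .data$task == "manipulation"))
  expect_warning(ind <- make_indicators(partial), "missing")
  expect_equal(nrow(ind), 2L)
})

test_that("exclusion needs low accuracy in both tasks, plus the SD rule", {
  mk <- function(id, acc1, acc2, rt = 2.5) {
    tibble::tibble(
      participant_id = id,
      task = rep(c("maintenance", "manipulation"), each = 40),
      trial = rep(1:40, 2), rt_s = rt,
      correct = c(rep(c(TRUE, FALSE), c(round(40 * acc1), 40 - round(40 * acc1))),
                  rep(c(TRUE, FALSE), c(round(40 * acc2), 40 - round(40 * acc2))))
    )
  }
  # enough regular participants that a genuine outlier can exceed 4 SD even
  # though it inflates the group SD itself (max z in a sample of n is
  # (n - 1) / sqrt(n), so small cohorts cannot trigger the rule at all)
  tbl <- dplyr::bind_rows(
    mk("low_both", 0.775, 0.775),
    mk("low_one", 0.775, 0.95),
    purrr::map(sprintf("ok%02d", 1:30), ~ mk(.x, 0.95, 0.95,
                                             rt = 2.5 + 0.01 * as.integer(substr(.x, 3, 4)))),
    mk("slowpoke", 0.95, 0.95, rt = 30)
  )
  res <- exclusion_filter(tbl)
  expect_true("low_both" %in% res$report$participant_id)
  expect_false("low_one" %in% res$report$participant_id)
  expect_true("slowpoke" %in% res$report$participant_id)
  expect_setequal(unique(res$data$participant_id),
                  c("low_one", sprintf("ok%02d", 1:30)))
})

test_that("descriptive contrast matches its analytic cases", {
  base <- generate_behavior(20, seed = 3)
  wide <- base |>
    dplyr::group_by(participant_id, task) |>
    dplyr::summarise(m = mean(rt_s), .groups = "drop") |>
    tidyr::pivot_wider(names_from = task, values_from = m)

  # identical columns: d = 0, r = 1
  same <- dplyr::bind_rows(
    tibble::tibble(participant_id = wide$participant_id, task = "maintenance",
                   trial = 1L, rt_s = wide$maintenance, correct = TRUE),
    tibble::tibble(participant_id = wide$participant_id, task = "manipulation",
                   trial = 1L, rt_s = wide$maintenance, correct = TRUE)
  )
  res_same <- describe_contrast(same)
  expect_equal(res_same$cohens_d, 0)
  expect_equal(res_same$pearson_r, 1)

  # antithetic participant means: r = -1
  anti <- dplyr::bind_rows(
    tibble::tibble(participant_id = wide$participant_id, task = "maintenance",
                   trial = 1L, rt_s = wide$maintenance, correct = TRUE),
    tibble::tibble(participant_id = wide$participant_id, task = "manipulation",
                   trial = 1L, rt_s = 10 - wide$maintenance, correct = TRUE)
  )
  expect_equal(describe_contrast(anti)$pearson_r, -1)

  # agreement with stats::t.test on the real table
  ref <- stats::t.test(wide$manipulation, wide$maintenance, paired = TRUE)
  res <- describe_contrast(base)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("effect-size recovery matches the planted standardized difference", {
  # planted d: mean gap over the SD of participant mean differences
  reps <- vapply(1:20, function(i) {
    b <- generate_behavior(64, mean_rt_task1 = 2.5, mean_rt_task2 = 2.9,
                           inter_factor_r = 0.65, seed = 4000 + i)
    describe_contrast(b)$cohens_d
  }, numeric(1))
  planted <- {
    b <- generate_behavior(4000, mean_rt_task1 = 2.5, mean_rt_task2 = 2.9,
                           inter_factor_r = 0.65, seed = 1)
    describe_contrast(b)$cohens_d
  }
  expect_gt(mean(abs(reps - planted) <= 0.3), 0.9)
})

test_that("CFA reproduces the identification convention's degrees of freedom", {
  b <- generate_behavior(200, seed = 5)
  ind <- make_indicators(b)
  two <- fit_factor_model(ind, wm_factor_spec)
  one <- fit_factor_model(ind, list(g = unlist(wm_factor_spec, use.names = FALSE)))
  expect_equal(two$df, 19L)
  expect_equal(one$df, 20L)
  expect_equal(two$n_free, 17L)
  expect_equal(one$n_free, 16L)
  # df arithmetic invariant
  expect_equal(two$df, two$p * (two$p + 1) / 2 - two$n_free)
  expect_true(two$chi_square >= 0)
})

test_that("the one-factor ML discrepancy matches factanal", {
  b <- generate_behavior(150, inter_factor_r = 0.8, seed = 6)
  ind <- make_indicators(b)
  one <- fit_factor_model(ind, list(g = unlist(wm_factor_spec, use.names = FALSE)))
  X <- as.matrix(ind[unlist(wm_factor_spec, use.names = FALSE)])
  fa <- stats::factanal(covmat = stats::cov(X), factors = 1, n.obs = nrow(X))
  expect_equal(one$discrepancy, unname(fa$criteria["objective"]), tolerance = 1e-4)
})

test_that("loadings are recovered from model-generated data", {
  lam <- c(0.25, 0.30, 0.35, 0.40)
  errs <- vapply(1:10, function(i) {
    b <- generate_behavior(1000, loadings_task1 = lam, loadings_task2 = rev(lam),
                           inter_factor_r = 0.5, unique_sd = 0.5, seed = 600 + i)
    fit <- fit_factor_model(make_indicators(b), wm_factor_spec)
    est <- abs(fit$loadings[cbind(1:8, rep(1:2, each = 4))])
    max(abs(est - c(lam, rev(lam))))
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})

test_that("tidy and glance expose the fitted parameters", {
  b <- generate_behavior(120, seed = 8)
  fit <- fit_factor_model(make_indicators(b), wm_factor_spec)
  td <- tidy(fit)
  expect_setequal(unique(td$type), c("loading", "factor_correlation", "uniqueness"))
  expect_equal(sum(td$type == "loading"), 8L)
  expect_equal(sum(td$type == "factor_correlation"), 1L)
  gl <- glance(fit)
  expect_equal(gl$df, 19L)
  expect_true(gl$converged)
})

test_that("the chi-square difference test behaves at its boundaries", {
  b <- generate_behavior(200, inter_factor_r = 0.65, seed = 9)
  ind <- make_indicators(b)
  cmp <- compare_factor_models(ind, wm_factor_spec)
  expect_equal(cmp$test$delta_df, 1L)
  expect_gte(cmp$test$delta_chi_square, 0)
  # identical fits: zero difference, p = 1 (restricted vs itself, df faked)
  one <- cmp$fit_one
  two_clone <- one; two_clone$df <- one$df - 1L
  same <- chisq_difference(one, two_clone)
  expect_equal(same$delta_chi_square, 0)
  expect_equal(same$p_value, 1)
  expect_error(chisq_difference(cmp$fit_two, cmp$fit_one), "df")
})

test_that("split-half analysis is deterministic and consistent under a stable truth", {
  b <- generate_behavior(120, inter_factor_r = 0.5, seed = 10)
  ind <- make_indicators(b)
  s1 <- split_half_consistency(ind, wm_factor_spec, split = "odd_even")
  s2 <- split_half_consistency(ind, wm_factor_spec, split = "odd_even")
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2L)
  expect_true(attr(s1, "consistent"))
  expect_error(split_half_consistency(ind[1:10, ], wm_factor_spec), "too few")
})

test_that("Heywood cases are bounded and flagged", {
  # two indicators nearly collinear force a boundary uniqueness
  withr::with_seed(12, {
    f <- stats::rnorm(80)
    X <- tibble::tibble(
      a = f + stats::rnorm(80, sd = 0.02),
      b = f + stats::rnorm(80, sd = 0.02),
      c = 0.5 * f + stats::rnorm(80),
      d = 0.4 * f + stats::rnorm(80)
    )
  })
  fit <- fit_factor_model(X, list(g = c("a", "b", "c", "d")))
  expect_true(fit$heywood)
  expect_true(all(fit$uniquenesses >= 0))
})
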