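#' Generate behavioural RT tables from a two-correlated-factor model
#'
#' Each participant has latent ability scores `(eta1, eta2)` drawn from a
#' bivariate standard normal with correlation `inter_factor_r`. A trial in
#' partition `q` of task `k` has
#' `rt = mean_rt_k + loadings_k[q] * eta_k + e`, `e ~ N(0, unique_sd)`.
#' With four partitions of `trials_per_partition` trials per task, the median
#' RT per partition recovers the classic eight-indicator, two-factor layout;
#' setting `inter_factor_r = 1` collapses the process to a single factor.
#'
#' @param n_participants Number of simulated participants.
#' @param loadings_task1,loadings_task2 Length-4 loading vectors (seconds per
#'   latent SD) for the four trial-order partitions of each task. The
#'   defaults, together with `unique_sd` and the task means, reproduce the
#'   hallmark behavioural profile of this paradigm: a ~1.3-s mean RT gap
#'   with a paired effect size near 1.5 and a moderate correlation between
#'   task means.
#' @param inter_factor_r Latent correlation in `[-1, 1]`.
#' @param unique_sd Trial-level residual SD in seconds (> 0 unless exactly 0
#'   for the degenerate noiseless case).
#' @param mean_rt_task1,mean_rt_task2 Task mean RTs in seconds.
#' @param trials_per_partition Trials per partition (>= 1); each task yields
#'   `4 * trials_per_partition` trials.
#' @param accuracy_task1,accuracy_task2 Per-trial probability of a correct
#'   response.
#' @param task_labels Labels for the two tasks.
#' @param seed Integer seed; identical arguments and seed give an identical
#'   table.
#' @return Tibble with columns `participant_id`, `task`, `trial`, `rt_s`,
#'   `correct`.
#' @export
generate_behavior <- function(n_participants,
                              loadings_task1 = rep(0.95, 4),
                              loadings_task2 = rep(0.95, 4),
                              inter_factor_r = 0.65,
                              unique_sd = 1.5,
                              mean_rt_task1 = 3.5, mean_rt_task2 = 4.8,
                              trials_per_partition = 10L,
                              accuracy_task1 = 0.93, accuracy_task2 = 0.90,
                              task_labels = c("maintenance", "manipulation"),
                              seed) {
  stopifnot(
    n_participants >= 1, trials_per_partition >= 1,
    abs(inter_factor_r) <= 1, unique_sd >= 0,
    length(loadings_task1) == 4, length(loadings_task2) == 4,
    all(is.finite(c(loadings_task1, loadings_task2))),
    length(task_labels) == 2
  )
  if (unique_sd < 0) stop("unique_sd must be non-negative", call. = FALSE)
  n_trials_task <- 4L * as.integer(trials_per_partition)
  withr::with_seed(as.integer(seed), {
    z <- matrix(stats::rnorm(2L * n_participants), ncol = 2L)
    eta2 <- inter_factor_r * z[, 1L] + sqrt(1 - inter_factor_r^2) * z[, 2L]
    eta <- cbind(z[, 1L], eta2)

    task_tbl <- function(k, loadings, mean_rt, acc) {
      partition <- rep(1:4, each = trials_per_partition)
      lam <- loadings[partition]
      rt <- rep(mean_rt, n_participants * n_trials_task) +
        rep(eta[, k], each = n_trials_task) * rep(lam, times = n_participants) +
        stats::rnorm(n_participants * n_trials_task, sd = unique_sd)
      tibble::tibble(
        participant_id = rep(sprintf("P%03d", seq_len(n_participants)),
                             each = n_trials_task),
        task = task_labels[k],
        trial = rep(seq_len(n_trials_task), times = n_participants),
        rt_s = pmax(rt, 0.05),
        correct = stats::runif(n_participants * n_trials_task) < acc
      )
    }
    dplyr::arrange(
      dplyr::bind_rows(
        task_tbl(1L, loadings_task1, mean_rt_task1, accuracy_task1),
        task_tbl(2L, loadings_task2, mean_rt_task2, accuracy_task2)
      ),
      .data$participant_id, .data$task, .data$trial
    )
  })
}
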