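#' Median-RT indicator table from trial-level behaviour
#'
#' Per participant and task, trials are ordered by trial index and divided
#' into `partitions` equal consecutive partitions; the median RT within each
#' partition becomes one indicator (robust to single lapses). Tasks named in
#' `set_size_tasks` are instead partitioned by their `set_size` column, one
#' indicator per set size. Participants missing any partition of a task are
#' excluded with a warning.
#'
#' @param table Trial-level tibble with `participant_id`, `task`, `trial`,
#'   `rt_s` (and `set_size` for span-type tasks).
#' @param partitions Number of trial-order partitions (default 4).
#' @param set_size_tasks Task labels partitioned by set size rather than
#'   trial order (default `"ospan"`).
#' @return Wide tibble, one row per participant, indicator columns named
#'   `<task>_p<partition>` (or `<task>_s<set_size>`).
#' @export
make_indicators <- function(table, partitions = 4L, set_size_tasks = "ospan") {
  stopifnot(partitions >= 1L,
            all(c("participant_id", "task", "trial", "rt_s") %in% names(table)))
  by_order <- table |>
    dplyr::filter(!(.data$task %in% set_size_tasks)) |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(partition = ceiling(dplyr::row_number() /
                                        (dplyr::n() / partitions))) |>
    dplyr::group_by(.data$participant_id, .data$task, .data$partition) |>
    dplyr::summarise(value = stats::median(.data$rt_s), .groups = "drop") |>
    dplyr::mutate(indicator = sprintf("%s_p%d", .data$task, .data$partition))
  span_rows <- table$task %in% set_size_tasks
  by_size <- if (any(span_rows)) {
    stopifnot("set_size" %in% names(table))
    table[span_rows, ] |>
      dplyr::group_by(.data$participant_id, .data$task, .data$set_size) |>
      dplyr::summarise(value = stats::median(.data$rt_s), .groups = "drop") |>
      dplyr::mutate(indicator = sprintf("%s_s%d", .data$task, .data$set_size))
  } else {
    tibble::tibble(participant_id = character(), indicator = character(),
                   value = numeric())
  }
  long <- dplyr::bind_rows(
    dplyr::select(by_order, "participant_id", "indicator", "value"),
    dplyr::select(by_size, "participant_id", "indicator", "value")
  )
  wide <- tidyr::pivot_wider(long, names_from = "indicator",
                             values_from = "value")
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warning(sprintf("%d participant(s) missing a partition; excluded", sum(!complete)),
            call. = FALSE)
    wide <- wide[complete, ]
  }
  wide
}

#' Participant exclusion by accuracy and RT outlier rules
#'
#' Removes participants whose accuracy falls below `accuracy_floor` in BOTH
#' working-memory tasks (a low score in only one task is retained), then
#' participants whose overall mean RT deviates more than `sd_k` standard
#' deviations from the group mean.
#'
#' @param table Trial-level behaviour tibble with a `correct` column.
#' @param accuracy_floor Per-task accuracy threshold (default 0.8).
#' @param sd_k RT outlier cut in group SDs (default 4).
#' @param wm_tasks The two task labels the accuracy rule applies to.
#' @return List: `data` (filtered tibble), `report` (tibble of removals with
#'   `participant_id`, `reason`).
#' @export
exclusion_filter <- function(table, accuracy_floor = 0.8, sd_k = 4,
                             wm_tasks = c("maintenance", "manipulation")) {
  acc <- table |>
    dplyr::filter(.data$task %in% wm_tasks) |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "task", values_from = "accuracy")
  low_both <- acc$participant_id[
    acc[[wm_tasks[1]]] < accuracy_floor & acc[[wm_tasks[2]]] < accuracy_floor]
  report <- tibble::tibble(participant_id = low_both,
                           reason = "accuracy below floor in both WM tasks")
  kept <- dplyr::filter(table, !(.data$participant_id %in% low_both))
  means <- kept |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_rt = mean(.data$rt_s), .groups = "drop")
  mu <- mean(means$mean_rt); sdev <- stats::sd(means$mean_rt)
  outliers <- if (is.finite(sdev) && sdev > 0) {
    means$participant_id[abs(means$mean_rt - mu) > sd_k * sdev]
  } else character(0)
  report <- dplyr::bind_rows(report, tibble::tibble(
    participant_id = outliers,
    reason = sprintf("mean RT beyond %g SD of group mean", sd_k)))
  list(data = dplyr::filter(kept, !(.data$participant_id %in% outliers)),
       report = report)
}

#' Paired descriptive contrast between two task conditions
#'
#' Participant-mean RT per task, then a paired t-test, paired Cohen's d
#' (`mean(diff) / sd(diff)`), and the Pearson correlation of the task means
#' across participants.
#'
#' @param table Trial-level behaviour tibble.
#' @param tasks Length-2 task labels; the difference is task2 - task1.
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p_value`, `cohens_d`,
#'   `pearson_r`, `n`.
#' @export
describe_contrast <- function(table, tasks = c("maintenance", "manipulation")) {
  wide <- table |>
    dplyr::filter(.data$task %in% tasks) |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::summarise(mean_rt = mean(.data$rt_s), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "task", values_from = "mean_rt")
  x <- wide[[tasks[1]]]; y <- wide[[tasks[2]]]
  stopifnot(length(x) >= 2L)
  d <- y - x
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(tibble::tibble(mean_diff = mean(d), t = NA_real_, df = length(d) - 1L,
                          p_value = NA_real_, cohens_d = 0,
                          pearson_r = suppressWarnings(stats::cor(x, y)),
                          n = length(d)))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  tibble::tibble(mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 cohens_d = mean(d) / sd_d,
                 pearson_r = stats::cor(x, y), n = length(d))
}
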