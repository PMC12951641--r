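#' Enumerate unordered channel pairs of a montage
#'
#' All `choose(n, 2)` unordered pairs in montage order; the backbone of the
#' directed-network statistics (496 pairs for the 32-channel montage).
#'
#' @param channels Character vector of channel names.
#' @return Tibble with columns `chan_a`, `chan_b` (`a` before `b` in montage
#'   order).
#' @export
channel_pairs <- function(channels = montage_32) {
  n <- length(channels)
  stopifnot(n >= 2L)
  idx <- utils::combn(n, 2L)
  tibble::tibble(chan_a = channels[idx[1L, ]], chan_b = channels[idx[2L, ]])
}

#' Full directed MI matrix of a recording
#'
#' MI for every ordered channel pair: entry (i, j) is the modulation of
#' channel j's high-frequency amplitude by channel i's low-frequency phase;
#' the diagonal holds within-electrode MI. Phase and amplitude series are
#' extracted once per channel, so the cost is linear in channels for the
#' filtering and quadratic only in the cheap binning step.
#'
#' @inheritParams mi_within
#' @return Tibble of class `mi_matrix` in long form: `phase_channel`,
#'   `amp_channel`, `mi`; attribute `channels` preserves montage order.
#' @export
mi_matrix <- function(recording, windows, phase_band = c(4, 8),
                      amp_band = c(40, 80), n_bins = 18L) {
  fs <- recording$fs_hz
  chans <- recording$channel_names
  idx <- select_window_samples(windows, fs, ncol(recording$signal))
  if (length(idx) == 0L) stop("no samples in analysis windows", call. = FALSE)
  width <- 2 * pi / n_bins
  bin_of <- function(ch) {
    phi <- band_series(recording, ch, phase_band, "phase")[idx]
    pmin(floor((wrap_phase(phi) + pi) / width) + 1L, n_bins)
  }
  phase_bins <- lapply(chans, bin_of)
  amps <- lapply(chans, function(ch)
    band_series(recording, ch, amp_band, "amplitude")[idx])
  grid <- tidyr::expand_grid(phase_channel = chans, amp_channel = chans)
  mi <- numeric(nrow(grid))
  k <- 0L
  for (i in seq_along(chans)) {
    ji <- phase_bins[[i]]
    counts <- tabulate(ji, nbins = n_bins)
    for (j in seq_along(chans)) {
      sums <- numeric(n_bins)
      rs <- rowsum(amps[[j]], ji)
      sums[as.integer(rownames(rs))] <- rs[, 1L]
      mean_amp <- ifelse(counts > 0L, sums / counts, 0)
      k <- k + 1L
      mi[k] <- mi_from_p(mean_amp / sum(mean_amp), n_bins)
    }
  }
  out <- grid
  out$mi <- mi
  attr(out, "channels") <- chans
  attr(out, "n_samples") <- length(idx)
  class(out) <- c("mi_matrix", class(out))
  out
}

#' Holm-Bonferroni step-down adjusted p-values
#'
#' The step-down procedure: sort raw p-values ascending, multiply the k-th by
#' `(m - k + 1)`, enforce monotonicity by running maxima, cap at 1. Controls
#' the family-wise error rate at least as well as Bonferroni while rejecting
#' a superset of Bonferroni's rejections. `NA` p-values are passed through
#' and do not count toward `m`.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  ord <- ok[order(p[ok])]
  adj <- pmin(cummax((m - seq_len(m) + 1L) * p[ord]), 1)
  out[ord] <- adj
  out
}

#' Directed coupling asymmetry network across a cohort
#'
#' For each unordered channel pair the directionality contrast
#' `dMI = MI(A -> B) - MI(B -> A)` is computed per participant (antisymmetric
#' by construction), tested against zero with a two-sided one-sample t-test
#' across the cohort, and Holm-Bonferroni corrected over all pairs.
#' Significant pairs become directed edges oriented by the sign of the mean
#' contrast, weighted by its absolute value. Pairs with zero variance across
#' participants are flagged (`NA` p).
#'
#' @param matrices List of `mi_matrix` tibbles, one per participant, on the
#'   same montage.
#' @param alpha Family-wise error level (default 0.05).
#' @return Tibble of class `directionality_result`: `chan_a`, `chan_b`,
#'   `mean_dmi`, `t`, `p_raw`, `p_adj`, `significant`, `source`, `target`,
#'   `weight`.
#' @export
directionality <- function(matrices, alpha = 0.05) {
  stopifnot(length(matrices) >= 3L, alpha > 0, alpha < 1)
  chans <- attr(matrices[[1]], "channels")
  pairs <- channel_pairs(chans)
  dmi <- vapply(matrices, function(m) {
    stopifnot(identical(attr(m, "channels"), chans))
    M <- matrix(m$mi, nrow = length(chans), byrow = TRUE,
                dimnames = list(chans, chans))
    ia <- match(pairs$chan_a, chans); ib <- match(pairs$chan_b, chans)
    M[cbind(ia, ib)] - M[cbind(ib, ia)]
  }, numeric(nrow(pairs)))
  dmi <- matrix(dmi, nrow = nrow(pairs))
  n <- ncol(dmi)
  mean_dmi <- rowMeans(dmi)
  sd_dmi <- apply(dmi, 1L, stats::sd)
  tstat <- ifelse(sd_dmi > 0, mean_dmi / (sd_dmi / sqrt(n)), NA_real_)
  p_raw <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  if (any(is.na(tstat))) {
    warning(sprintf("%d pair(s) with zero variance across participants; p undefined",
                    sum(is.na(tstat))), call. = FALSE)
  }
  p_adj <- holm_adjust(p_raw)
  sig <- !is.na(p_adj) & p_adj <= alpha
  out <- pairs
  out$mean_dmi <- mean_dmi
  out$t <- tstat
  out$p_raw <- p_raw
  out$p_adj <- p_adj
  out$significant <- sig
  out$source <- ifelse(mean_dmi >= 0, pairs$chan_a, pairs$chan_b)
  out$target <- ifelse(mean_dmi >= 0, pairs$chan_b, pairs$chan_a)
  out$weight <- abs(mean_dmi)
  attr(out, "n_participants") <- n
  attr(out, "alpha") <- alpha
  attr(out, "dmi") <- dmi
  class(out) <- c("directionality_result", class(out))
  out
}

#' Extract the significant directed edge list
#'
#' @param result A `directionality_result`.
#' @return Tibble `source`, `target`, `weight`, `t`, `p_adj` for significant
#'   pairs only.
#' @export
network_edges <- function(result) {
  stopifnot(inherits(result, "directionality_result"))
  dplyr::select(
    dplyr::filter(tibble::as_tibble(result), .data$significant),
    "source", "target", "weight", "t", "p_adj"
  )
}

#' Between-task contrast of directionality with exclusive edge sets
#'
#' Paired t-tests per unordered pair on the per-participant directionality
#' contrast between two task conditions, Holm-Bonferroni corrected, plus the
#' edges significant exclusively in each task's own directionality network.
#'
#' @param matrices_task1,matrices_task2 Per-participant `mi_matrix` lists for
#'   the two conditions (same participants, same order).
#' @param alpha Family-wise error level.
#' @return List: `contrast` (per-pair paired-test tibble),
#'   `network_task1`/`network_task2` (each task's [directionality()] result),
#'   `exclusive_task1`/`exclusive_task2` (edge tibbles).
#' @export
task_contrast <- function(matrices_task1, matrices_task2, alpha = 0.05) {
  stopifnot(length(matrices_task1) == length(matrices_task2),
            length(matrices_task1) >= 3L)
  net1 <- directionality(matrices_task1, alpha)
  net2 <- directionality(matrices_task2, alpha)
  d1 <- attr(net1, "dmi"); d2 <- attr(net2, "dmi")
  diff <- d1 - d2
  n <- ncol(diff)
  m <- rowMeans(diff)
  s <- apply(diff, 1L, stats::sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p_raw <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  contrast <- channel_pairs(attr(matrices_task1[[1]], "channels"))
  contrast$mean_diff <- m
  contrast$t <- tstat
  contrast$p_raw <- p_raw
  contrast$p_adj <- holm_adjust(p_raw)
  contrast$significant <- !is.na(contrast$p_adj) & contrast$p_adj <= alpha
  edge_key <- function(net) paste(net$source, net$target)[net$significant]
  e1 <- network_edges(net1); e2 <- network_edges(net2)
  list(
    contrast = contrast,
    network_task1 = net1, network_task2 = net2,
    exclusive_task1 = e1[!(paste(e1$source, e1$target) %in% edge_key(net2)), ],
    exclusive_task2 = e2[!(paste(e2$source, e2$target) %in% edge_key(net1)), ]
  )
}

#' Strongest modulating sources of a target electrode
#'
#' Ranks source channels by group-mean cross-electrode MI(source -> target)
#' and returns the top `k`. Ties break by montage order, deterministically.
#'
#' @param matrices List of `mi_matrix` tibbles.
#' @param target_channel Target (amplitude) channel name.
#' @param k Number of sources to return (0 gives an empty tibble).
#' @return Tibble `source`, `mean_mi`, ranked.
#' @export
strongest_modulators <- function(matrices, target_channel, k = 3L) {
  stopifnot(length(matrices) >= 1L, k >= 0L)
  chans <- attr(matrices[[1]], "channels")
  stopifnot(target_channel %in% chans)
  long <- dplyr::bind_rows(matrices)
  ranked <- long |>
    dplyr::filter(.data$amp_channel == target_channel,
                  .data$phase_channel != target_channel) |>
    dplyr::group_by(source = .data$phase_channel) |>
    dplyr::summarise(mean_mi = mean(.data$mi), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_mi), match(.data$source, chans))
  ranked[seq_len(min(k, nrow(ranked))), ]
}
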