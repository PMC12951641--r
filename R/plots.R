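#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a comodulogram
#'
#' Heat map of MI over the phase-frequency by amplitude-frequency grid; for
#' group results, cells exceeding the permutation threshold are outlined.
#'
#' @param object A `comodulogram` or `comodulogram_group` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comodulogram
#' @export
autoplot.comodulogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$phase_mid <- (df$phase_low_hz + df$phase_high_hz) / 2
  df$amp_mid <- (df$amp_low_hz + df$amp_high_hz) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$phase_mid, .data$amp_mid,
                                        fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI") +
    ggplot2::labs(x = "Phase frequency (Hz)", y = "Amplitude frequency (Hz)") +
    ggplot2::theme_minimal()
  if ("significant" %in% names(df) && any(df$significant)) {
    p <- p + ggplot2::geom_tile(data = df[df$significant, ],
                                fill = NA, colour = "white", linewidth = 0.8)
  }
  p
}

#' @rdname autoplot.comodulogram
#' @method autoplot comodulogram_group
#' @export
autoplot.comodulogram_group <- autoplot.comodulogram

#' Plot a time-frequency map
#'
#' @param object A `tfr_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfr_map
#' @export
autoplot.tfr_map <- function(object, ...) {
  df <- tidyr::expand_grid(freq_hz = object$freqs_hz, time_s = object$times_s)
  df$magnitude <- as.vector(t(object$magnitude))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c(name = "|CWT|") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a directed coupling network
#'
#' Channels on a circle, significant directed edges as arrows with width
#' proportional to the coupling-asymmetry weight.
#'
#' @param object A `directionality_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot directionality_result
#' @export
autoplot.directionality_result <- function(object, ...) {
  chans <- unique(c(object$chan_a, object$chan_b))
  ang <- seq(0, 2 * pi, length.out = length(chans) + 1L)[seq_along(chans)]
  pos <- tibble::tibble(channel = chans, x = cos(ang), y = sin(ang))
  edges <- network_edges(object)
  p <- ggplot2::ggplot(pos, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), vjust = -1, size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_void()
  if (nrow(edges) > 0L) {
    seg <- dplyr::left_join(edges, pos, by = c(source = "channel")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(pos, by = c(target = "channel"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linewidth = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      colour = "grey30", alpha = 0.8) +
      ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none")
  }
  p
}

#' Plot per-participant MI by task condition
#'
#' @param mi_table Tibble with `participant`, `task`, `mi` columns (e.g. the
#'   `mi` element of a [run_pipeline()] result).
#' @return A ggplot object.
#' @export
plot_mi_by_task <- function(mi_table) {
  ggplot2::ggplot(mi_table, ggplot2::aes(.data$task, .data$mi)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       alpha = 0.4, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::labs(x = NULL, y = "Modulation index") +
    ggplot2::theme_minimal()
}
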