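#' Plot factor-activity time courses
#'
#' Line plot of activity against time, one panel per factor.
#'
#' @param object A `tfa_activity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfa_activity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$alpha)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2c6fbb") +
    ggplot2::facet_wrap(~tf, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = expression(alpha),
                  title = "Transcription factor activities") +
    ggplot2::theme_minimal()
}

#' Plot periodicity scores
#'
#' @param object A `tfa_periodicity` tibble.
#' @param threshold Retention threshold drawn as a reference line
#'   (default 0.44).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfa_periodicity <- function(object, threshold = 0.44, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$score)
  df$tf <- factor(df$tf, levels = df$tf)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$tf)) +
    ggplot2::geom_col(fill = "#2c6fbb") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Periodicity score", y = NULL,
                  title = "Periodicity at the one-cycle lag") +
    ggplot2::theme_minimal()
}

#' Polar plot of sine-fit phases and amplitudes
#'
#' Each factor is drawn at its fitted phase angle with radius equal to the
#' fitted amplitude, the standard view of phase ordering around the
#' metabolic cycle.
#'
#' @param sine_fits Tibble from [fit_sines()].
#' @return A ggplot object.
#' @export
plot_phase_polar <- function(sine_fits) {
  ggplot2::ggplot(sine_fits,
                  ggplot2::aes(x = .data$phase_deg, y = .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$phase_deg, yend = 0),
                          colour = "grey70") +
    ggplot2::geom_point(colour = "#2c6fbb", size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$tf), size = 3,
                       vjust = -0.8) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, 30)) +
    ggplot2::labs(x = "Phase (degrees)", y = "Amplitude",
                  title = "Best-fit sine phases and amplitudes") +
    ggplot2::theme_minimal()
}

#' Plot a regulatory network
#'
#' Nodes on a circle, directed edges as arrows; edge colour encodes sign
#' and width encodes |weight|. Self-loops are omitted.
#'
#' @param object A `tfa_network` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfa_network <- function(object, ...) {
  edges <- network_export_edges(object, include_self_loops = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to, object$factor_ids)))
  angle <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble::tibble(name = nodes, x = cos(angle), y = sin(angle))
  seg <- dplyr::left_join(edges, layout, by = c("from" = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c("to" = "name")) |>
    dplyr::mutate(sign_lab = ifelse(.data$sign >= 0, "positive", "negative"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$sign_lab,
                   linewidth = abs(.data$weight)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      alpha = 0.7
    ) +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name), size = 3) +
    ggplot2::scale_colour_manual(values = c(positive = "#2c6fbb",
                                            negative = "firebrick")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "Sign", linewidth = "|weight|",
                  title = "Regulatory network from the time-translation matrix") +
    ggplot2::theme_void()
}

#' Plot an oxygen trace with cycle-phase labels
#'
#' @param cycle_labels Tibble from [classify_cycle_phases_from_oxygen()].
#' @param oxygen_trace Raw trace aligned to the same grid.
#' @return A ggplot object.
#' @export
plot_cycle_phases <- function(cycle_labels, oxygen_trace) {
  df <- dplyr::mutate(cycle_labels, oxygen = as.numeric(oxygen_trace))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$oxygen)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::scale_colour_manual(values = c("Ox" = "firebrick",
                                            "R/B" = "#2c6fbb",
                                            "R/C" = "darkgreen")) +
    ggplot2::labs(x = "Time (min)", y = "Dissolved oxygen",
                  colour = "Cycle phase",
                  title = "Metabolic-cycle phases from the oxygen trace") +
    ggplot2::theme_minimal()
}
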