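#' Plot normalized readout trajectories
#'
#' One line per chamber, coloured by treatment, with the exposure window
#' shaded and the control baseline at 1. Expects a (typically doubly
#' normalized) series tibble.
#'
#' @param series Series tibble: `chamber_id`, `treatment`, `time_h`,
#'   `value`.
#' @param window Exposure window to shade (default 72-216 h).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(series, window = phase_windows()$treatment) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               group = .data$chamber_id,
                               colour = .data$treatment)) +
    ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (h)", y = "Normalized value",
                  colour = "Treatment") +
    ggplot2::theme_minimal()
}

#' Volcano plot of gene-family changes
#'
#' @param object An `mbra_volcano` tibble from [volcano()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbra_volcano <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$q),
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "forestgreen", ns = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-4, 4), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change (treated / control)",
                  y = "-log10 q value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Impact heatmap of the screen
#'
#' Treatments on the x axis ordered from lowest to highest impact score,
#' readouts on the y axis, tiles coloured by reversibility class.
#'
#' @param object An `mbra_impact` from [build_impact_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbra_impact <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(treatment = factor(.data$treatment,
                                     levels = object$ranking$treatment))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$treatment, y = .data$readout,
                                   fill = .data$class)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(none = "grey90", reversible = "goldenrod2",
                 non_reversible = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Phase AUC dot plot
#'
#' Per-chamber phase AUCs by treatment, faceted by readout and phase, with
#' the flat-control reference line (the AUC a constant-1 trajectory would
#' give) drawn per phase.
#'
#' @param object An `mbra_auc` tibble from [score_readout()] or
#'   [score_experiment()].
#' @param windows Phase windows used for the reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbra_auc <- function(object, windows = phase_windows(), ...) {
  ref <- tibble(phase = names(windows),
                ref = vapply(windows, diff, numeric(1)))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$treatment, y = .data$auc,
                                       colour = .data$treatment)) +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$ref),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1),
                        show.legend = FALSE) +
    ggplot2::facet_grid(readout ~ phase, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "AUC (value-hours)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
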