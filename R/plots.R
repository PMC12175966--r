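#' Box-and-whisker plot of per-session movement metrics by condition
#'
#' Median line, 25/75% box, whiskers to minimum and maximum — the
#' conventions of the open-field movement figures.
#'
#' @param sessions Per-session tibble with `condition` and a metric column.
#' @param metric Column to plot (default `"walking_distance_m"`).
#' @return A ggplot object.
#' @export
plot_condition_boxes <- function(sessions, metric = "walking_distance_m") {
  if (!metric %in% names(sessions)) stop_config("column `%s` not found.", metric)
  ggplot2::ggplot(sessions,
                  ggplot2::aes(x = .data$condition, y = .data[[metric]],
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(coef = Inf, show.legend = FALSE) +
    ggplot2::labs(x = "condition", y = metric) +
    ggplot2::theme_minimal()
}

#' Arena trajectory coloured by angular speed
#'
#' @param object A `"kinematics"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinematics
#' @export
autoplot.kinematics <- function(object, ...) {
  ggplot2::ggplot(object$frames,
                  ggplot2::aes(x = .data$x_cm, y = .data$y_cm,
                               colour = .data$ang_speed_rad_s)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = "angular\nspeed (rad/s)") +
    ggplot2::theme_minimal()
}

#' Stacked percentage bars of neuron classification labels
#'
#' @param classifications Output of [classify_neurons()] (or a
#'   [proportion_summary()] tibble).
#' @return A ggplot object.
#' @export
plot_classification_proportions <- function(classifications) {
  props <- if (all(c("label", "percent") %in% names(classifications))) {
    classifications
  } else {
    proportion_summary(classifications)
  }
  ggplot2::ggplot(props,
                  ggplot2::aes(x = .data$comparison, y = .data$percent,
                               fill = .data$label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(increased = "#c0392b",
                                          decreased = "#2980b9",
                                          other = "grey70")) +
    ggplot2::labs(x = NULL, y = "% of neurons") +
    ggplot2::theme_minimal()
}

#' Median fluorescence rate per condition, consistent-trend neurons highlighted
#'
#' One line per neuron across the on / off / fixed conditions; neurons with
#' consistently increased rates in red, consistently decreased in blue.
#'
#' @param trend Output of [trend_analysis()].
#' @return A ggplot object.
#' @export
plot_trend_medians <- function(trend) {
  long <- trend |>
    tidyr::pivot_longer(c("median_on", "median_off", "median_fixed"),
                        names_to = "condition", values_to = "median_rate",
                        names_prefix = "median_") |>
    mutate(condition = factor(.data$condition, levels = c("on", "off", "fixed")))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$condition, y = .data$median_rate,
                               group = .data$neuron_id, colour = .data$trend)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(consistent_up = "#c0392b",
                                            consistent_down = "#2980b9",
                                            none = "grey75")) +
    ggplot2::labs(x = NULL, y = "median fluorescence rate (dF/F)") +
    ggplot2::theme_minimal()
}

#' Torque and commutator traces from a commutator simulation
#'
#' @param object A `"poec_sim"` object.
#' @param ... Unused.
#' @return A ggplot object (torque trace with the threshold marked).
#' @method autoplot poec_sim
#' @export
autoplot.poec_sim <- function(object, ...) {
  ggplot2::ggplot(object$ticks,
                  ggplot2::aes(x = .data$time_s, y = .data$torque_mNm)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$config$torque_threshold,
                        linetype = "dashed", colour = "#c0392b") +
    ggplot2::labs(x = "time (s)", y = "tether torque (mN·m)") +
    ggplot2::theme_minimal()
}
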