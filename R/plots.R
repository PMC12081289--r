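# Diagnostic ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rate map
#'
#' @param object A [ratemap()].
#' @param ... Unused.
#' @return A ggplot raster of the map in its native coordinates.
#' @export
autoplot.ratemap <- function(object, ...) {
  df <- tidy.ratemap(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "Hz") +
    ggplot2::theme_minimal()
}

#' Plot replay visit-efficiency curves
#'
#' @param curves Tibble from [exp_replay_visits()] or
#'   [replay_visit_curve()].
#' @return A ggplot of success against per-state replay visit, one panel per
#'   trajectory mode and one colour per agent.
#' @export
plot_visit_curves <- function(curves) {
  ggplot2::ggplot(
    curves,
    ggplot2::aes(.data$visit, .data$success, colour = .data$agent)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "replay visit to state", y = "policy success") +
    ggplot2::theme_minimal()
}

#' Plot homing-error grids
#'
#' @param homing Tidy tibble from [homing_experiment()].
#' @return A ggplot heat map of mean homing error over the experiment grids.
#' @export
plot_homing_grid <- function(homing) {
  df <- homing |>
    dplyr::mutate(cond = ifelse(.data$experiment == "noise_by_length",
      .data$length, .data$replays
    )) |>
    dplyr::summarise(error = mean(.data$error),
      .by = c("experiment", "agent", "noise", "cond")
    )
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$noise), factor(.data$cond),
    fill = .data$error
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$experiment),
      cols = ggplot2::vars(.data$agent)
    ) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::labs(
      x = "path-integration noise", y = "exploration length / replays",
      fill = "homing error"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an aligned change-map summary
#'
#' @param summary Result of [summarize_session_changes()].
#' @return A ggplot of the radial change profiles per replay group with
#'   s.e.m. ribbons.
#' @export
plot_change_profiles <- function(summary) {
  df <- summary$profile |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      .by = c("group", "radius")
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$radius, .data$mean, colour = .data$group)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem,
        fill = .data$group
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from replay spike (cm)", y = "rate change (Hz)") +
    ggplot2::theme_minimal()
}
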