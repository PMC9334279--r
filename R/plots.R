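#' Plot a mid-plane slice of a volume
#'
#' Heatmap of one slice of a [vox_volume()] (pressure, intensity, HU or
#' temperature), in millimetre coordinates.
#'
#' @param object A [vox_volume()].
#' @param slice_axis Axis perpendicular to the displayed plane (default 3).
#' @param slice_index Slice index; default the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vox_volume <- function(object, slice_axis = 3, slice_index = NULL,
                                ...) {
  d <- dim(object$data)
  if (is.null(slice_index)) slice_index <- ceiling(d[slice_axis] / 2)
  keep <- setdiff(1:3, slice_axis)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[slice_axis]] <- slice_index
  sl <- object$data[idx[[1]], idx[[2]], idx[[3]]]
  # first axis varies fastest, matching column-major array order
  df <- tibble::as_tibble(expand.grid(
    a = axis_coords(object, keep[1]) * 1e3,
    b = axis_coords(object, keep[2]) * 1e3))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("axis ", keep[1], " (mm)"),
                  y = paste0("axis ", keep[2], " (mm)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pressure_field <- function(object, ...) {
  autoplot.vox_volume(object$p_pp, ...) +
    ggplot2::labs(title = "Steady-state peak-to-peak pressure")
}

#' Plot the probe temperature-elevation time course
#'
#' @param object A `thermal_result` from [solve_bioheat()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thermal_result <- function(object, ...) {
  ggplot2::ggplot(object$probe, ggplot2::aes(.data$t_s / 60, .data$dT)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = expression(Delta * T ~ "(K)"),
                  title = "Probe temperature elevation") +
    ggplot2::theme_minimal()
}

#' Plot per-section tracer uptake by group
#'
#' Companion plot for [quantify_sections()] outputs pooled over animals and
#' groups: mean percent uptake per section offset with standard-error bars,
#' faceted by tracer.
#'
#' @param data A tibble with columns `section_offset_mm`, `tracer`,
#'   `percent_uptake` and a grouping column.
#' @param group Grouping column (tidy-eval).
#' @return A ggplot object.
#' @export
plot_uptake_profile <- function(data, group) {
  summ <- data |>
    dplyr::group_by(.data$tracer, .data$section_offset_mm, {{ group }}) |>
    dplyr::summarise(
      mean_uptake = mean(.data$percent_uptake),
      se = stats::sd(.data$percent_uptake) /
        sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$section_offset_mm,
                                     .data$mean_uptake,
                                     colour = {{ group }})) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_uptake - .data$se,
                                          ymax = .data$mean_uptake + .data$se)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tracer), scales = "free_y") +
    ggplot2::labs(x = "section offset (mm)", y = "% uptake") +
    ggplot2::theme_minimal()
}
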