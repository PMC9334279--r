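#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the pairwise comparisons of a group_stats fit
#'
#' @param x A [group_stats()] object.
#' @param ... Unused.
#' @return A tibble with one row per Tukey HSD contrast.
#' @export
tidy.group_stats <- function(x, ...) x$tukey

#' One-row model summary of a group_stats fit
#'
#' @param x A [group_stats()] object.
#' @param ... Unused.
#' @return A one-row tibble with the ANOVA F statistic, degrees of freedom
#'   and p value.
#' @export
glance.group_stats <- function(x, ...) x$anova

#' Tidy focus metrics into a one-row tibble (millimetres)
#'
#' @param x A [focus_metrics()] object.
#' @param ... Unused.
#' @return A one-row tibble with focal position and widths in mm.
#' @export
tidy.focus_metrics <- function(x, ...) {
  tibble::tibble(
    focal_x_mm = x$focal_position_m[1] * 1e3,
    focal_y_mm = x$focal_position_m[2] * 1e3,
    focal_z_mm = x$focal_position_m[3] * 1e3,
    focal_distance_from_exit_plane_mm =
      x$focal_distance_from_exit_plane_m * 1e3,
    axial_fwhm_mm = x$axial_fwhm_m * 1e3,
    lateral_fwhm_mm = x$lateral_fwhm_m * 1e3,
    axial_fw90_mm = x$axial_fw90_m * 1e3,
    lateral_fw90_mm = x$lateral_fw90_m * 1e3,
    max_on_boundary = x$max_on_boundary)
}

#' Tidy the probe series of a thermal result
#'
#' @param x A `thermal_result` from [solve_bioheat()].
#' @param ... Unused.
#' @return The probe tibble (`t_s`, `temp_c`, `dT`).
#' @export
tidy.thermal_result <- function(x, ...) x$probe

#' One-row summary of a thermal result
#'
#' @param x A `thermal_result`.
#' @param ... Unused.
#' @return A one-row tibble: `peak_dT`, `t95_s`, `duration_s`,
#'   `time_step_s`.
#' @export
glance.thermal_result <- function(x, ...) {
  t95 <- tryCatch(steady_state_time(x), error = function(e) NA_real_,
                  warning = function(w) suppressWarnings(steady_state_time(x)))
  tibble::tibble(peak_dT = x$peak_dT, t95_s = t95,
                 duration_s = max(x$probe$t_s), time_step_s = x$time_step_s)
}
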