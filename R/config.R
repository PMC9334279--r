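#' Read a simulation configuration file
#'
#' Parses a YAML configuration with optional blocks `sonication:`,
#' `transducer:` and `skull_mapping:` into the corresponding package objects.
#'
#' The `sonication:` block takes keys `ff_hz`, `pd_s`, `prf_hz`,
#' `duration_s` and exactly one amplitude key among `ispta_w_cm2`,
#' `isppa_w_cm2`, `pr_kpa`. The `transducer:` block takes
#' `aperture_diameter_m`, `curvature_radius_m`, optional `position_m`,
#' `axis`. The `skull_mapping:` block takes any argument of
#' [property_mapping()].
#'
#' @param path Path to a YAML file.
#' @return A list with any of `sonication` ([pulse_train()]), `transducer`
#'   ([transducer_geometry()]), `skull_mapping` ([property_mapping()]), plus
#'   the raw parsed list as `raw`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(raw = raw)
  if (!is.null(raw$sonication)) {
    s <- raw$sonication
    amp <- list()
    if (!is.null(s$ispta_w_cm2)) amp$ispta_w_cm2 <- s$ispta_w_cm2
    if (!is.null(s$isppa_w_cm2)) amp$isppa_w_cm2 <- s$isppa_w_cm2
    if (!is.null(s$pr_kpa)) amp$pr_pa <- s$pr_kpa * 1e3
    if (length(amp) != 1) {
      stop("sonication block needs exactly one amplitude key ",
           "(ispta_w_cm2, isppa_w_cm2 or pr_kpa)", call. = FALSE)
    }
    out$sonication <- do.call(pulse_train, c(
      list(ff_hz = s$ff_hz, pd_s = s$pd_s, prf_hz = s$prf_hz,
           duration_s = s$duration_s), amp))
  }
  if (!is.null(raw$transducer)) {
    tr <- raw$transducer
    out$transducer <- transducer_geometry(
      aperture_diameter_m = tr$aperture_diameter_m %||% 0.028,
      curvature_radius_m = tr$curvature_radius_m %||% 0.022,
      position_m = tr$position_m %||% c(0, 0, 0),
      axis = tr$axis %||% c(1, 0, 0))
  }
  if (!is.null(raw$skull_mapping)) {
    out$skull_mapping <- do.call(property_mapping, raw$skull_mapping)
  }
  out
}
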