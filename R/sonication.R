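#' Pulsed-sonication parameter set
#'
#' Constructs the temporal description of a pulsed focused-ultrasound exposure:
#' bursts of a sinusoidal carrier at the fundamental frequency, each lasting one
#' pulse duration (PD), repeated at the pulse repetition frequency (PRF) for the
#' overall sonication duration. Exactly one amplitude specification is attached:
#' spatial-peak pulse-average intensity (`isppa_w_cm2`), spatial-peak
#' temporal-average intensity (`ispta_w_cm2`), peak-rarefactional pressure
#' (`pr_pa`) or peak-to-peak pressure (`pp_pa`).
#'
#' Pulses must not overlap: `pd_s * prf_hz <= 1`, with equality meaning
#' continuous wave (CW).
#'
#' @param ff_hz Fundamental (carrier) frequency in Hz.
#' @param pd_s Pulse duration in seconds.
#' @param prf_hz Pulse repetition frequency in Hz.
#' @param duration_s Total sonication duration in seconds.
#' @param isppa_w_cm2,ispta_w_cm2,pr_pa,pp_pa Amplitude specification; supply
#'   exactly one.
#' @return An object of class `pulse_train`.
#' @examples
#' # 100 ms pulses once per second (10% duty cycle), the in-vivo scheme
#' pt <- pulse_train(200e3, pd_s = 0.1, prf_hz = 1, duration_s = 1800,
#'                   ispta_w_cm2 = 0.5)
#' duty_cycle(pt)
#' @export
pulse_train <- function(ff_hz, pd_s, prf_hz, duration_s,
                        isppa_w_cm2 = NULL, ispta_w_cm2 = NULL,
                        pr_pa = NULL, pp_pa = NULL) {
  amp <- list(isppa_w_cm2 = isppa_w_cm2, ispta_w_cm2 = ispta_w_cm2,
              pr_pa = pr_pa, pp_pa = pp_pa)
  amp <- amp[!vapply(amp, is.null, logical(1))]
  if (length(amp) != 1L) {
    stop("supply exactly one amplitude specification ",
         "(isppa_w_cm2, ispta_w_cm2, pr_pa or pp_pa)", call. = FALSE)
  }
  vals <- c(ff_hz = ff_hz, pd_s = pd_s, prf_hz = prf_hz,
            duration_s = duration_s, amp = amp[[1]])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all pulse-train fields must be finite and strictly positive",
         call. = FALSE)
  }
  if (pd_s * prf_hz > 1 + 1e-12) {
    stop("pulses overlap: pd_s * prf_hz = ", format(pd_s * prf_hz),
         " exceeds 1", call. = FALSE)
  }
  structure(
    list(ff_hz = ff_hz, pd_s = pd_s, prf_hz = prf_hz,
         duration_s = duration_s,
         amplitude = list(kind = names(amp), value = amp[[1]])),
    class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat("<pulse_train> ", x$ff_hz / 1e3, " kHz carrier, PD ",
      x$pd_s * 1e3, " ms @ PRF ", x$prf_hz, " Hz (DC ",
      round(100 * duty_cycle(x), 2), "%), duration ", x$duration_s, " s, ",
      x$amplitude$kind, " = ", x$amplitude$value, "\n", sep = "")
  invisible(x)
}

#' Water acoustic constants
#'
#' Characteristic acoustic impedance inputs for plane-wave pressure-intensity
#' relations. Defaults are degassed water at 24 degrees C, matching a
#' room-temperature bath.
#'
#' @param density_kg_m3 Mass density in kg/m^3.
#' @param sound_speed_m_s Longitudinal sound speed in m/s.
#' @return An object of class `medium_constants`.
#' @export
medium_constants <- function(density_kg_m3 = 997, sound_speed_m_s = 1494) {
  if (density_kg_m3 <= 0 || sound_speed_m_s <= 0) {
    stop("density and sound speed must be positive", call. = FALSE)
  }
  structure(list(density_kg_m3 = density_kg_m3,
                 sound_speed_m_s = sound_speed_m_s),
            class = "medium_constants")
}

#' Sonication duty cycle
#'
#' The active-sonication fraction per pulse period, DC = PD x PRF. Equals 1 for
#' continuous wave.
#'
#' @param pt A [pulse_train()].
#' @return Duty cycle as a fraction in (0, 1].
#' @export
duty_cycle <- function(pt) {
  stopifnot(inherits(pt, "pulse_train"))
  min(pt$pd_s * pt$prf_hz, 1)
}

#' Convert between pulse-average and temporal-average intensity
#'
#' At duty cycle DC, the temporal-average intensity is the pulse-average
#' intensity diluted by the active fraction: I_SPTA = I_SPPA x DC. These two
#' helpers are exact inverses of each other.
#'
#' @param ispta_w_cm2,isppa_w_cm2 Intensity in W/cm^2.
#' @param dc Duty cycle, a fraction in (0, 1].
#' @return Intensity in W/cm^2.
#' @examples
#' isppa_for_ispta(0.5, 0.10)  # 5 W/cm2: the 10% DC in-vivo setting
#' @export
isppa_for_ispta <- function(ispta_w_cm2, dc) {
  check_dc(dc)
  ispta_w_cm2 / dc
}

#' @rdname isppa_for_ispta
#' @export
ispta_from_isppa <- function(isppa_w_cm2, dc) {
  check_dc(dc)
  isppa_w_cm2 * dc
}

check_dc <- function(dc) {
  if (any(dc <= 0 | dc > 1)) {
    stop("duty cycle must lie in (0, 1]", call. = FALSE)
  }
  invisible(dc)
}

#' Plane-wave pressure from intensity
#'
#' For a travelling plane wave of pulse-average intensity I in a medium of
#' characteristic impedance rho*c, the peak (rarefactional) pressure is
#' P_r = sqrt(2 rho c I) and the peak-to-peak pressure is 2 P_r (linear
#' regime). Intensity here is per-pulse (I_SPPA), so the conversion is
#' independent of duty cycle.
#'
#' @param intensity_w_cm2 Intensity in W/cm^2.
#' @param medium A [medium_constants()].
#' @param convention `"peak-rarefactional"` (default) or `"peak-to-peak"`.
#' @return Pressure in Pa.
#' @examples
#' pressure_from_intensity(5, medium_constants()) / 1e3  # ~386 kPa
#' @export
pressure_from_intensity <- function(intensity_w_cm2,
                                    medium = medium_constants(),
                                    convention = c("peak-rarefactional",
                                                   "peak-to-peak")) {
  convention <- match.arg(convention)
  if (any(intensity_w_cm2 <= 0)) stop("intensity must be positive", call. = FALSE)
  i_w_m2 <- intensity_w_cm2 * 1e4
  pr <- sqrt(2 * medium$density_kg_m3 * medium$sound_speed_m_s * i_w_m2)
  if (convention == "peak-to-peak") 2 * pr else pr
}

#' Plane-wave intensity from pressure
#'
#' Exact inverse of [pressure_from_intensity()]: I = P_r^2 / (2 rho c), with
#' P_r = P_pp / 2 under the peak-to-peak convention.
#'
#' @param pressure_pa Pressure in Pa.
#' @inheritParams pressure_from_intensity
#' @return Intensity in W/cm^2.
#' @export
intensity_from_pressure <- function(pressure_pa,
                                    medium = medium_constants(),
                                    convention = c("peak-rarefactional",
                                                   "peak-to-peak")) {
  convention <- match.arg(convention)
  if (any(pressure_pa <= 0)) stop("pressure must be positive", call. = FALSE)
  pr <- if (convention == "peak-to-peak") pressure_pa / 2 else pressure_pa
  pr^2 / (2 * medium$density_kg_m3 * medium$sound_speed_m_s) / 1e4
}

#' Binary pulse envelope
#'
#' The on/off gating of the carrier: 1 during the first PD of each PRF period,
#' 0 otherwise. Its time average over one period equals the duty cycle.
#'
#' @param pt A [pulse_train()].
#' @param t_s Time points in seconds, each within `[0, duration_s]`.
#' @return Integer vector of 0/1 values, one per time point.
#' @export
pulse_envelope <- function(pt, t_s) {
  stopifnot(inherits(pt, "pulse_train"))
  if (any(t_s < 0 | t_s > pt$duration_s)) {
    stop("t_s must lie within [0, duration_s]", call. = FALSE)
  }
  phase <- t_s %% (1 / pt$prf_hz)
  as.integer(phase < pt$pd_s)
}

#' Acoustic wavelength
#'
#' lambda = c / f. At 200 kHz in water (c ~ 1500 m/s) this is ~7.5 mm,
#' comparable to the rodent cranial dimension — the geometric origin of the
#' intracranial reverberation this package simulates.
#'
#' @param f_hz Frequency in Hz.
#' @param c_m_s Sound speed in m/s.
#' @return Wavelength in metres.
#' @export
wavelength <- function(f_hz, c_m_s) {
  if (any(f_hz <= 0) || any(c_m_s <= 0)) {
    stop("frequency and sound speed must be positive", call. = FALSE)
  }
  c_m_s / f_hz
}

#' Tabulate a constant-I_SPTA pulsing series
#'
#' For a set of duty cycles at a fixed temporal-average intensity, computes the
#' pulse-average intensity each condition requires, together with the PRF (at
#' fixed PD) or PD (at fixed PRF) that realizes the duty cycle, and the
#' peak-rarefactional pressure in the reference medium. This reproduces the
#' standard bench-characterization tables for a pulsed exposure series.
#'
#' @param dc Duty cycles as fractions in (0, 1].
#' @param ispta_w_cm2 The fixed temporal-average intensity in W/cm^2.
#' @param pd_s Fixed pulse duration in s, or `NULL` if `prf_hz` is fixed.
#' @param prf_hz Fixed PRF in Hz, or `NULL` if `pd_s` is fixed.
#' @param medium A [medium_constants()] for the pressure column.
#' @return A tibble with columns `dc_percent`, `pd_ms`, `prf_hz`,
#'   `ispta_w_cm2`, `isppa_w_cm2`, `pr_kpa`.
#' @examples
#' sonication_table(c(.10, .25, .50, .75, 1), ispta_w_cm2 = 0.5, prf_hz = 1)
#' @export
sonication_table <- function(dc, ispta_w_cm2 = 0.5, pd_s = NULL,
                             prf_hz = NULL, medium = medium_constants()) {
  check_dc(dc)
  if (is.null(pd_s) == is.null(prf_hz)) {
    stop("fix exactly one of pd_s or prf_hz", call. = FALSE)
  }
  if (is.null(pd_s)) pd_s <- dc / prf_hz else prf_hz <- dc / pd_s
  isppa <- isppa_for_ispta(ispta_w_cm2, dc)
  tibble::tibble(
    dc_percent = 100 * dc,
    pd_ms = 1e3 * pd_s,
    prf_hz = prf_hz,
    ispta_w_cm2 = ispta_w_cm2,
    isppa_w_cm2 = isppa,
    pr_kpa = pressure_from_intensity(isppa, medium) / 1e3)
}
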