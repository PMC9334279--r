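#' Tissue and blood thermal constants
#'
#' Per-tissue thermal properties for the Pennes bioheat solver. Specific heat
#' and conductivity defaults: brain 3600 J/kg/K and 0.528 W/K/m, skull
#' 1300 J/kg/K and 0.4 W/K/m; blood perfusion 8.24 kg/m^3/s with blood
#' density 1030 kg/m^3 and specific heat 3620 J/kg/K; arterial and initial
#' temperature 37.5 degrees C. Brain and skull densities are not part of that
#' constant set; 1040 and 1900 kg/m^3 are adopted and configurable.
#'
#' @param brain,skull,water Per-tissue lists with `density_kg_m3`,
#'   `specific_heat_j_kg_k`, `conductivity_w_m_k`.
#' @param blood List with `perfusion_kg_m3_s`, `density_kg_m3`,
#'   `specific_heat_j_kg_k`, `arterial_temp_c`.
#' @param initial_temp_c Initial tissue temperature, degrees C.
#' @return A list of class `thermal_properties`.
#' @export
thermal_properties <- function(
    brain = list(density_kg_m3 = 1040, specific_heat_j_kg_k = 3600,
                 conductivity_w_m_k = 0.528),
    skull = list(density_kg_m3 = 1900, specific_heat_j_kg_k = 1300,
                 conductivity_w_m_k = 0.4),
    water = list(density_kg_m3 = 997, specific_heat_j_kg_k = 4180,
                 conductivity_w_m_k = 0.6),
    blood = list(perfusion_kg_m3_s = 8.24, density_kg_m3 = 1030,
                 specific_heat_j_kg_k = 3620, arterial_temp_c = 37.5),
    initial_temp_c = 37.5) {
  props <- list(brain = brain, skull = skull, water = water, blood = blood,
                initial_temp_c = initial_temp_c)
  flat <- unlist(props)
  if (any(!is.finite(flat)) ||
      any(flat[!grepl("temp", names(flat))] < 0)) {
    stop("thermal properties must be finite and non-negative", call. = FALSE)
  }
  structure(props, class = "thermal_properties")
}

#' Voxelwise thermal grid
#'
#' Expands per-tissue constants onto the voxel grid of a `material_grid`
#' (labels: 0 water/soft, 1 brain, 2 skull). Perfusion applies to brain
#' voxels by default; water and (optionally) bone are unperfused.
#'
#' @param mat A `material_grid`, or `NULL` when `label` is given directly.
#' @param props A [thermal_properties()].
#' @param label Optional integer label array (overrides `mat$label`).
#' @param spacing_m,origin_m Grid geometry when `mat` is `NULL`.
#' @param perfused_labels Labels whose voxels carry the perfusion sink.
#' @return A list of class `thermal_grid` with arrays `rho_ct` (volumetric
#'   heat capacity, J/m^3/K), `conductivity`, `wb_cb` (perfusion x blood heat
#'   capacity, W/m^3/K), plus `spacing_m`, `origin_m`, `arterial_temp_c`,
#'   `initial_temp_c`.
#' @export
thermal_grid <- function(mat = NULL, props = thermal_properties(),
                         label = NULL, spacing_m = NULL, origin_m = c(0, 0, 0),
                         perfused_labels = 1L) {
  if (is.null(label)) {
    stopifnot(inherits(mat, "material_grid"))
    label <- mat$label
    spacing_m <- mat$spacing_m
    origin_m <- mat$origin_m
  }
  d <- dim(label)
  pick <- function(field) {
    c(props$water[[field]], props$brain[[field]], props$skull[[field]])[label + 1L]
  }
  rho <- array(pick("density_kg_m3"), d)
  ct <- array(pick("specific_heat_j_kg_k"), d)
  kc <- array(pick("conductivity_w_m_k"), d)
  wb <- array(0, d)
  wb[label %in% perfused_labels] <-
    props$blood$perfusion_kg_m3_s * props$blood$specific_heat_j_kg_k
  structure(list(rho_ct = rho * ct, conductivity = kc, wb_cb = wb,
                 spacing_m = spacing_m, origin_m = as.numeric(origin_m),
                 arterial_temp_c = props$blood$arterial_temp_c,
                 initial_temp_c = props$initial_temp_c),
            class = "thermal_grid")
}

#' Acoustic heat source
#'
#' Volumetric power deposition from the absorbed acoustic field,
#' `q = 2 alpha I`. In `"duty-averaged"` mode the constant source
#' `q = 2 alpha I_SPTA` is returned; in `"pulse-resolved"` mode the peak
#' source `q = 2 alpha I_SPPA` is returned together with the pulse envelope
#' parameters so the solver can gate it. The two modes deposit identical
#' energy over each pulse period.
#'
#' @param isppa A [vox_volume()] of I_SPPA in W/cm^2, or an `intensity_field`.
#' @param absorption_np_m Amplitude absorption coefficient, Np/m (scalar or
#'   array).
#' @param pulse A [pulse_train()].
#' @param mode `"duty-averaged"` or `"pulse-resolved"`.
#' @return A [vox_volume()] of power density (W/m^3) with attributes `mode`,
#'   `pd_s`, `prf_hz`.
#' @export
heat_source <- function(isppa, absorption_np_m, pulse,
                        mode = c("duty-averaged", "pulse-resolved")) {
  mode <- match.arg(mode)
  if (inherits(isppa, "intensity_field")) isppa <- isppa$isppa_w_cm2
  stopifnot(inherits(isppa, "vox_volume"))
  if (any(absorption_np_m < 0)) stop("absorption must be non-negative",
                                     call. = FALSE)
  dc <- duty_cycle(pulse)
  i_w_m2 <- isppa$data * 1e4
  q <- if (mode == "duty-averaged") 2 * absorption_np_m * i_w_m2 * dc
       else 2 * absorption_np_m * i_w_m2
  out <- vox_volume(q, isppa$spacing_m, isppa$origin_m, unit = "W/m3")
  attr(out, "mode") <- mode
  attr(out, "pd_s") <- pulse$pd_s
  attr(out, "prf_hz") <- pulse$prf_hz
  out
}

#' Bioheat solver configuration
#'
#' @param time_step_s Explicit step, or `NULL`: 90% of the diffusion
#'   stability bound `min(rho c dx^2 / (6 k))` in duty-averaged mode, capped
#'   at 0.5 ms in pulse-resolved mode.
#' @param duration_s Simulated sonication duration (default 1800 s, a 30 min
#'   exposure).
#' @param boundary `"dirichlet"` (outer faces pinned at the arterial
#'   temperature) or `"insulated"`.
#' @param probe_m Probe position (m); `NULL` uses the source maximum.
#' @param record_every_s Probe sampling interval; `NULL` gives ~400 samples.
#' @return A list of class `bioheat_config`.
#' @export
bioheat_config <- function(time_step_s = NULL, duration_s = 1800,
                           boundary = c("dirichlet", "insulated"),
                           probe_m = NULL, record_every_s = NULL) {
  boundary <- match.arg(boundary)
  structure(list(time_step_s = time_step_s, duration_s = duration_s,
                 boundary = boundary, probe_m = probe_m,
                 record_every_s = record_every_s), class = "bioheat_config")
}

#' Solve the Pennes bioheat equation
#'
#' Explicit FDTD integration of
#' `rho c_t dT/dt = div(k grad T) + q - w_b c_b (T - T_a)`
#' from a uniform initial temperature, under either a constant (duty-averaged)
#' or pulse-gated heat source. Refuses to run if the explicit stability bound
#' is violated.
#'
#' @param q Heat source from [heat_source()] (or any [vox_volume()] in W/m^3).
#' @param tg A [thermal_grid()].
#' @param cfg A [bioheat_config()].
#' @return An object of class `thermal_result`: `probe` (tibble `t_s`,
#'   `temp_c`, `dT`), `peak_series` (tibble of the volume-wide maximum over
#'   time), `peak_dT` (K), `T_final` ([vox_volume()], degrees C),
#'   `probe_index`, `time_step_s`.
#' @export
solve_bioheat <- function(q, tg, cfg = bioheat_config()) {
  stopifnot(inherits(q, "vox_volume"), inherits(tg, "thermal_grid"))
  d <- dim(tg$rho_ct)
  if (!identical(dim(q$data), d)) {
    stop("heat source and thermal grid dimensions differ", call. = FALSE)
  }
  dx <- tg$spacing_m
  bound <- min(tg$rho_ct / (6 * tg$conductivity)) * dx^2
  mode <- attr(q, "mode") %||% "duty-averaged"
  pulsed <- identical(mode, "pulse-resolved")
  dt <- cfg$time_step_s
  if (is.null(dt)) dt <- if (pulsed) min(0.9 * bound, 5e-4) else 0.9 * bound
  if (dt > bound) {
    stop("explicit stability violated: time step ", format(dt),
         " s exceeds the diffusion bound ", format(bound), " s", call. = FALSE)
  }
  probe_m <- cfg$probe_m
  if (is.null(probe_m)) {
    im <- which.max(q$data)
    probe_idx0 <- im - 1L
  } else {
    probe_idx0 <- linear_index0(
      list(density_kg_m3 = tg$rho_ct, spacing_m = dx, origin_m = tg$origin_m),
      matrix(probe_m, 1))
  }
  nsteps <- ceiling(cfg$duration_s / dt)
  rec <- cfg$record_every_s
  record_every <- if (is.null(rec)) max(1L, floor(nsteps / 400)) else
    max(1L, round(rec / dt))

  res <- bioheat_kernel(as.numeric(tg$rho_ct), as.numeric(tg$conductivity),
                        as.numeric(tg$wb_cb), as.numeric(q$data),
                        as.integer(d), dx, dt, cfg$duration_s,
                        tg$initial_temp_c, tg$arterial_temp_c,
                        probe_idx0, as.integer(record_every),
                        cfg$boundary == "dirichlet", pulsed,
                        attr(q, "pd_s") %||% 1, attr(q, "prf_hz") %||% 1)

  structure(list(
    probe = tibble::tibble(t_s = res$probe_t, temp_c = res$probe_T,
                           dT = res$probe_T - tg$initial_temp_c),
    peak_series = tibble::tibble(t_s = res$probe_t,
                                 dT_max = res$peak_T_series - tg$initial_temp_c),
    peak_dT = res$peak_T - tg$initial_temp_c,
    T_final = vox_volume(array(res$T_final, d), dx, tg$origin_m, unit = "degC"),
    probe_index = probe_idx0 + 1L, time_step_s = dt,
    initial_temp_c = tg$initial_temp_c), class = "thermal_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thermal_result <- function(x, ...) {
  cat("<thermal_result> peak dT = ", signif(x$peak_dT, 4), " K over ",
      max(x$probe$t_s), " s (dt = ", x$time_step_s, " s)\n", sep = "")
  invisible(x)
}

#' Time to reach steady state
#'
#' First time at which the probe temperature elevation reaches `level` of its
#' final value; the final sample is taken as the steady state. Warns if the
#' series has visibly not levelled off (more than 2% relative growth over its
#' last tenth).
#'
#' @param result A `thermal_result`.
#' @param level Fraction of the final elevation (default 0.95).
#' @return Time in seconds.
#' @export
steady_state_time <- function(result, level = 0.95) {
  stopifnot(inherits(result, "thermal_result"), level > 0, level < 1)
  s <- result$probe
  dT_end <- s$dT[nrow(s)]
  if (dT_end <= 0) stop("no temperature elevation at the probe", call. = FALSE)
  tail_start <- s$dT[max(1, floor(0.9 * nrow(s)))]
  if ((dT_end - tail_start) / dT_end > 0.02) {
    warning("probe series has not converged: elevation still growing ",
            "over the final tenth of the run", call. = FALSE)
  }
  s$t_s[which(s$dT >= level * dT_end)[1]]
}

#' Gaussian heat source on a cube of homogeneous tissue
#'
#' Convenience generator for the thermal benchmark used throughout the
#' package: an isotropic 3D Gaussian duty-averaged power deposition
#' `q(r) = 2 alpha I0 exp(-r^2 / (2 sigma^2))` centred in a cube of a single
#' tissue. Its no-perfusion steady state has the closed form
#' `dT(0) = 2 alpha I0 sigma^2 / k`.
#'
#' @param side_m Cube edge length, m.
#' @param spacing_m Voxel spacing, m.
#' @param sigma_m Gaussian width, m.
#' @param i0_w_cm2 Peak intensity (temporal-average, W/cm^2).
#' @param absorption_np_m Amplitude absorption, Np/m.
#' @return A list with the source `q` ([vox_volume()], W/m^3) and the brain
#'   `label` array.
#' @export
gaussian_heat_cube <- function(side_m = 0.040, spacing_m = 0.5e-3,
                               sigma_m = 2.1e-3, i0_w_cm2 = 0.65,
                               absorption_np_m = 0.25) {
  n <- round(side_m / spacing_m) + 1
  x <- (seq_len(n) - 1) * spacing_m - side_m / 2
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  q0 <- 2 * absorption_np_m * i0_w_cm2 * 1e4
  q <- vox_volume(q0 * exp(-r2 / (2 * sigma_m^2)), spacing_m,
                  c(x[1], x[1], x[1]), unit = "W/m3")
  attr(q, "mode") <- "duty-averaged"
  list(q = q, label = array(1L, rep(n, 3)))
}
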