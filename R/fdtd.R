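#' FDTD solver configuration
#'
#' Numerical controls for [run_fdtd()]. When `time_step_s` is `NULL` the step
#' is chosen as the largest value that (a) satisfies the CFL condition
#' `dt <= dx / (sqrt(nd) * c_max)` with a 0.8 safety factor (`nd` = number of
#' active dimensions; the margin keeps the lossy sponge layer inside the
#' stability region) and (b) divides the carrier period into an integer
#' number of steps, so the steady-state detector can work on whole periods.
#'
#' @param time_step_s Explicit time step in seconds, or `NULL` for automatic.
#' @param steady_tol Relative change of the per-period focal peak below which
#'   the field is declared steady (default 0.5%).
#' @param min_periods,max_periods Bounds on the number of carrier periods
#'   simulated; `NULL` derives `min_periods` from two domain transit times.
#' @param sponge_wavelengths Absorbing-layer thickness in wavelengths
#'   (default 1).
#' @param ramp_periods Cosine-taper source onset length in periods.
#' @return A list of class `fdtd_config`.
#' @export
fdtd_config <- function(time_step_s = NULL, steady_tol = 0.005,
                        min_periods = NULL, max_periods = NULL,
                        sponge_wavelengths = 1, ramp_periods = 2) {
  structure(as.list(environment()), class = "fdtd_config")
}

# resolve dt / steps-per-period / sponge for a given grid and frequency
resolve_fdtd_cfg <- function(cfg, mat, f_hz) {
  d <- dim(mat$density_kg_m3)
  nd <- sum(d > 1)
  cmax <- max(mat$sound_speed_m_s)
  cfl <- mat$spacing_m / (sqrt(nd) * cmax)
  if (is.null(cfg$time_step_s)) {
    spp <- ceiling(1 / (f_hz * 0.8 * cfl))
    dt <- 1 / (f_hz * spp)
  } else {
    dt <- cfg$time_step_s
    if (dt > cfl + 1e-18) {
      stop("CFL violation: time step ", format(dt), " s exceeds the bound ",
           format(cfl), " s for dx = ", mat$spacing_m * 1e3, " mm and c_max = ",
           cmax, " m/s", call. = FALSE)
    }
    spp <- max(8L, round(1 / (f_hz * dt)))
    dt <- 1 / (f_hz * spp)  # snap to an integer number of steps per period
  }
  c_ref <- stats::median(mat$sound_speed_m_s)
  lam <- c_ref / f_hz
  n_sponge <- max(8L, ceiling(cfg$sponge_wavelengths * lam / mat$spacing_m))
  sigma_max <- 8 * c_ref / (n_sponge * mat$spacing_m)
  min_p <- cfg$min_periods
  if (is.null(min_p)) {
    transit <- max(d * mat$spacing_m) / min(mat$sound_speed_m_s)
    min_p <- ceiling(2 * transit * f_hz) + 4
  }
  max_p <- cfg$max_periods
  if (is.null(max_p)) max_p <- 4 * min_p + 20
  list(dt = dt, spp = as.integer(spp), n_sponge = as.integer(n_sponge),
       sigma_max = sigma_max, min_periods = as.integer(min_p),
       max_periods = as.integer(max_p), steady_tol = cfg$steady_tol,
       ramp_periods = cfg$ramp_periods)
}

# snap world positions (n x 3, metres) to 0-based linear voxel indices
linear_index0 <- function(mat, pos) {
  d <- dim(mat$density_kg_m3)
  idx <- sweep(pos, 2, mat$origin_m)
  idx <- round(idx / mat$spacing_m)
  idx <- pmin(pmax(idx, 0), matrix(rep(d - 1L, each = nrow(pos)), ncol = 3))
  as.integer(idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3]))
}

#' Run the heterogeneous acoustic FDTD simulation
#'
#' Propagates the harmonic drive of a focused bowl source through the material
#' grid with a first-order pressure-velocity staggered-grid scheme, until the
#' per-period peak pressure at the geometric focus stabilizes, then records
#' the per-voxel peak-to-peak pressure over one further full carrier period.
#' Attenuation is a first-order loss on the velocity update (exact for a
#' single frequency); boundaries are an exponential-damping sponge layer.
#'
#' The bowl is injected as additive monopole sources on its surface voxels,
#' with volume velocity `2 u0 A_j` per patch (the factor 2 renders each patch
#' equivalent to a baffled simple source, matching the Rayleigh-Sommerfeld
#' reference of [freefield_pressure()]), and a per-patch phase correction for
#' the sub-voxel snap of patch centres. The output is linear in `u0_m_s`.
#'
#' @param mat A `material_grid` (see [build_material_grid()],
#'   [homogeneous_material_grid()]).
#' @param geom A [transducer_geometry()]; the axis must be grid-aligned for
#'   downstream profile metrics, but the solver itself has no such constraint.
#' @param f_hz Drive frequency, Hz.
#' @param u0_m_s Uniform surface velocity amplitude, m/s.
#' @param cfg An [fdtd_config()].
#' @param patches_per_wavelength Bowl discretization density.
#' @return An object of class `pressure_field`: `p_pp` (a [vox_volume()] of
#'   peak-to-peak pressure, Pa, zeroed inside the sponge margin), `converged`,
#'   `periods`, `focus_peaks`, `focus_trace`, `focus_index`, `n_sponge`.
#' @export
run_fdtd <- function(mat, geom, f_hz, u0_m_s = 1, cfg = fdtd_config(),
                     patches_per_wavelength = 8) {
  stopifnot(inherits(mat, "material_grid"),
            inherits(geom, "transducer_geometry"))
  rc <- resolve_fdtd_cfg(cfg, mat, f_hz)
  d <- dim(mat$density_kg_m3)
  dx <- mat$spacing_m

  # discretize the bowl in the medium local to the source
  src_vox0 <- linear_index0(mat, matrix(geom$position_m, 1))
  c_src <- mat$sound_speed_m_s[src_vox0 + 1]
  lam <- c_src / f_hz
  patches <- discretize_bowl(geom, lam, patches_per_wavelength)
  pos <- as.matrix(patches[, c("x", "y", "z")])
  idx0 <- linear_index0(mat, pos)
  if (any(is.na(idx0))) stop("source patches fall outside the grid", call. = FALSE)

  # phase-correct each patch for the sub-voxel snap, referenced to the focus
  focus <- geom$position_m + geom$curvature_radius_m * geom$axis
  snap <- cbind((idx0 %% d[1]), (idx0 %/% d[1]) %% d[2], idx0 %/% (d[1] * d[2]))
  snap <- sweep(snap * dx, 2, mat$origin_m, "+")
  r_exact <- sqrt(rowSums(sweep(pos, 2, focus)^2))
  r_snap <- sqrt(rowSums(sweep(snap, 2, focus)^2))
  k <- 2 * pi * f_hz / c_src
  phase <- k * (r_snap - r_exact)

  # monopole injection amplitude: dt * rho * c^2 * Q / dx^3, Q = 2 u0 A
  rho_v <- mat$density_kg_m3[idx0 + 1]
  c_v <- mat$sound_speed_m_s[idx0 + 1]
  amp <- rc$dt * rho_v * c_v^2 * (2 * u0_m_s * patches$area_m2) / dx^3
  # merge patches snapping to the same voxel coherently
  z <- amp * exp(1i * phase)
  zs <- rowsum(cbind(Re(z), Im(z)), idx0)
  idx_u <- as.integer(rownames(zs))
  zc <- complex(real = zs[, 1], imaginary = zs[, 2])

  focus_idx0 <- linear_index0(mat, matrix(focus, 1))

  res <- fdtd_kernel(as.numeric(mat$density_kg_m3),
                     as.numeric(mat$sound_speed_m_s),
                     as.numeric(mat$attenuation_np_m),
                     as.integer(d), dx, rc$dt, f_hz,
                     idx_u, Mod(zc), Arg(zc),
                     rc$spp, rc$min_periods, rc$max_periods, rc$steady_tol,
                     rc$n_sponge, rc$sigma_max, focus_idx0, rc$ramp_periods)

  ppk <- array(res$p_pp, d)
  ppk <- zero_margin(ppk, rc$n_sponge)
  structure(list(
    p_pp = vox_volume(ppk, dx, mat$origin_m, unit = "Pa"),
    converged = res$converged, periods = res$periods,
    focus_peaks = res$focus_peaks, focus_trace = res$focus_trace,
    focus_index = focus_idx0 + 1L, n_sponge = rc$n_sponge,
    time_step_s = rc$dt, f_hz = f_hz), class = "pressure_field")
}

# zero a margin of m voxels along every active (length > 1) dimension
zero_margin <- function(arr, m) {
  d <- dim(arr)
  for (ax in which(d > 1)) {
    n <- d[ax]
    mm <- min(m, floor((n - 1) / 2))
    if (mm < 1) next
    idx <- c(seq_len(mm), n - seq_len(mm) + 1)
    if (ax == 1) arr[idx, , ] <- 0
    if (ax == 2) arr[, idx, ] <- 0
    if (ax == 3) arr[, , idx] <- 0
  }
  arr
}

#' @export
print.pressure_field <- function(x, ...) {
  cat("<pressure_field> ", if (x$converged) "converged" else
      "NOT converged", " after ", x$periods, " periods\n", sep = "")
  cat("  max P_pp: ", signif(max(x$p_pp$data) / 1e3, 5), " kPa\n", sep = "")
  invisible(x)
}

#' One-dimensional FDTD on a layered medium
#'
#' Plane-wave variant of [run_fdtd()] used for verification against the
#' closed-form Fresnel transmission coefficient `T = 2 Z2 / (Z1 + Z2)` and
#' Beer-Lambert attenuation `e^(-alpha L)`. A monopole line source near the
#' left sponge launches a rightward plane wave through the stacked layers.
#'
#' @param layers A data frame with columns `length_m`, `density_kg_m3`,
#'   `sound_speed_m_s`, `attenuation_np_m`, ordered left to right.
#' @param f_hz Drive frequency, Hz.
#' @param spacing_m Grid spacing; default `lambda_min / 30`.
#' @param cfg An [fdtd_config()].
#' @return A `pressure_field` whose `p_pp` is `n x 1 x 1`; additionally
#'   carries `interfaces_m`, the world coordinates of the layer boundaries.
#' @export
run_fdtd_1d <- function(layers, f_hz, spacing_m = NULL, cfg = fdtd_config()) {
  stopifnot(all(c("length_m", "density_kg_m3", "sound_speed_m_s",
                  "attenuation_np_m") %in% names(layers)))
  lam_min <- min(layers$sound_speed_m_s) / f_hz
  if (is.null(spacing_m)) spacing_m <- lam_min / 30
  lam_pad <- max(layers$sound_speed_m_s) / f_hz    # room for sponge + source
  n_pad <- ceiling(1.5 * lam_pad / spacing_m)
  bnd <- cumsum(layers$length_m)
  n_core <- ceiling(sum(layers$length_m) / spacing_m)
  n <- n_core + 2 * n_pad
  x <- (seq_len(n) - 1) * spacing_m - n_pad * spacing_m
  lay <- findInterval(x, c(-Inf, bnd[-length(bnd)]))
  lay[lay < 1] <- 1
  grid <- make_grid(c(n, 1, 1), spacing_m, c(x[1], 0, 0))
  mat <- homogeneous_material_grid(grid)
  mat$density_kg_m3[] <- layers$density_kg_m3[lay]
  mat$sound_speed_m_s[] <- layers$sound_speed_m_s[lay]
  mat$attenuation_np_m[] <- layers$attenuation_np_m[lay]

  rc <- resolve_fdtd_cfg(cfg, mat, f_hz)
  src0 <- rc$n_sponge + 2L                 # just inside the left sponge
  probe0 <- as.integer(round(n / 2)) - 1L
  amp <- rc$dt * mat$density_kg_m3[src0 + 1] * mat$sound_speed_m_s[src0 + 1]^2 /
    spacing_m
  res <- fdtd_kernel(as.numeric(mat$density_kg_m3),
                     as.numeric(mat$sound_speed_m_s),
                     as.numeric(mat$attenuation_np_m),
                     c(n, 1L, 1L), spacing_m, rc$dt, f_hz,
                     src0, amp, 0,
                     rc$spp, rc$min_periods, rc$max_periods, rc$steady_tol,
                     rc$n_sponge, rc$sigma_max, probe0, rc$ramp_periods)
  ppk <- zero_margin(array(res$p_pp, c(n, 1, 1)), rc$n_sponge)
  structure(list(
    p_pp = vox_volume(ppk, spacing_m, c(x[1], 0, 0), unit = "Pa"),
    converged = res$converged, periods = res$periods,
    focus_peaks = res$focus_peaks, focus_trace = res$focus_trace,
    focus_index = probe0 + 1L, n_sponge = rc$n_sponge,
    time_step_s = rc$dt, f_hz = f_hz,
    interfaces_m = bnd[-length(bnd)]), class = "pressure_field")
}

#' Intensity maps from a pressure field
#'
#' Converts the steady-state peak-to-peak pressure into per-voxel intensities
#' using the local plane-wave relation `I_SPPA = (P_pp/2)^2 / (2 rho c)`, the
#' temporal-average map `I_SPTA = I_SPPA x DC`, and the relative map
#' normalized to its maximum.
#'
#' @param pf A `pressure_field` from [run_fdtd()], or a [vox_volume()] of
#'   peak-to-peak pressure in Pa.
#' @param mat The `material_grid` the field was computed on.
#' @param pulse A [pulse_train()] supplying the duty cycle.
#' @return An object of class `intensity_field` with [vox_volume()] members
#'   `isppa_w_cm2`, `ispta_w_cm2`, `relative`, plus `duty_cycle`.
#' @export
intensity_map <- function(pf, mat, pulse) {
  if (inherits(pf, "vox_volume")) {
    pf <- structure(list(p_pp = pf, focus_index = which.max(pf$data)),
                    class = "pressure_field")
  }
  stopifnot(inherits(pf, "pressure_field"), inherits(mat, "material_grid"))
  if (!identical(dim(pf$p_pp$data), dim(mat$density_kg_m3))) {
    stop("pressure field and material grid dimensions differ", call. = FALSE)
  }
  dc <- duty_cycle(pulse)
  isppa <- (pf$p_pp$data / 2)^2 /
    (2 * mat$density_kg_m3 * mat$sound_speed_m_s) / 1e4
  rel <- if (max(isppa) > 0) isppa / max(isppa) else isppa
  sp <- pf$p_pp$spacing_m; or <- pf$p_pp$origin_m
  structure(list(
    isppa_w_cm2 = vox_volume(isppa, sp, or, unit = "W/cm2"),
    ispta_w_cm2 = vox_volume(isppa * dc, sp, or, unit = "W/cm2"),
    relative = vox_volume(rel, sp, or, unit = ""),
    duty_cycle = dc), class = "intensity_field")
}

#' Rescale a pressure field to a target focal pulse-average intensity
#'
#' Uses solver linearity: multiplies the whole field by the factor that makes
#' the intensity at `at_index` (default the stored focus voxel) equal
#' `target_isppa_w_cm2`.
#'
#' @param pf A `pressure_field`.
#' @param mat The matching `material_grid`.
#' @param target_isppa_w_cm2 Target intensity, W/cm^2.
#' @param at_index Linear voxel index at which the target applies.
#' @return The rescaled `pressure_field`.
#' @export
scale_to_isppa <- function(pf, mat, target_isppa_w_cm2,
                           at_index = pf$focus_index) {
  rho <- mat$density_kg_m3[at_index]
  cs <- mat$sound_speed_m_s[at_index]
  p_target <- 2 * pressure_from_intensity(
    target_isppa_w_cm2, medium_constants(rho, cs))
  fac <- p_target / pf$p_pp$data[at_index]
  pf$p_pp$data <- pf$p_pp$data * fac
  pf$focus_trace <- pf$focus_trace * fac
  pf$focus_peaks <- pf$focus_peaks * fac
  pf
}
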