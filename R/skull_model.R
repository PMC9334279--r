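#' Calibrate CT values against a water reference
#'
#' Shifts the whole volume so the mean value inside the water region of
#' interest is exactly 0 HU, the Hounsfield definition of water. micro-CT
#' volumes acquired with a water calibration tube in the field of view are
#' calibrated this way before any property mapping. The operation is an affine
#' shift, hence idempotent and offset-preserving.
#'
#' @param ct A [vox_volume()] of CT values.
#' @param water_roi Logical array of the same dimension marking water voxels.
#' @return The calibrated [vox_volume()] (unit "HU").
#' @export
calibrate_hu <- function(ct, water_roi) {
  stopifnot(inherits(ct, "vox_volume"))
  if (!is.logical(water_roi) || !identical(dim(water_roi), dim(ct$data))) {
    stop("water_roi must be a logical array matching the CT dimensions",
         call. = FALSE)
  }
  n <- sum(water_roi)
  if (n == 0) stop("water_roi is empty", call. = FALSE)
  out <- ct
  out$data <- ct$data - mean(ct$data[water_roi])
  out$unit <- "HU"
  out
}

# linear interpolation of a 3D array along one axis at new coordinates
resample_axis <- function(arr, old, new, axis) {
  i1 <- findInterval(new, old, rightmost.closed = TRUE)
  i1 <- pmin(pmax(i1, 1L), length(old) - 1L)
  w <- (new - old[i1]) / (old[i1 + 1L] - old[i1])
  w <- pmin(pmax(w, 0), 1)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  out <- m[i1, , drop = FALSE] * (1 - w) + m[i1 + 1L, , drop = FALSE] * w
  a2 <- array(out, c(length(new), d[2], d[3]))
  aperm(a2, order(perm))
}

#' Resample a volume to coarser isotropic spacing
#'
#' Trilinear (separable linear) interpolation onto a coarser isotropic grid,
#' as used to bring micro-CT resolution down to the simulation grid. The
#' default 0.25 mm target gives 30 voxels per 7.5 mm wavelength at 200 kHz in
#' water.
#'
#' @param vol A [vox_volume()].
#' @param target_spacing_m Target spacing in metres; must be >= the native
#'   spacing.
#' @return The resampled [vox_volume()].
#' @export
resample_isotropic <- function(vol, target_spacing_m = 0.25e-3) {
  stopifnot(inherits(vol, "vox_volume"))
  if (target_spacing_m <= 0) stop("target spacing must be positive", call. = FALSE)
  if (target_spacing_m < vol$spacing_m - 1e-12) {
    stop("resample_isotropic only coarsens: target spacing below native ",
         "spacing", call. = FALSE)
  }
  d <- dim(vol$data)
  arr <- vol$data
  for (ax in 1:3) {
    old <- (seq_len(d[ax]) - 1) * vol$spacing_m
    new <- seq(0, old[length(old)], by = target_spacing_m)
    arr <- resample_axis(arr, old, new, ax)
  }
  vox_volume(arr, target_spacing_m, vol$origin_m, unit = vol$unit)
}

#' Hounsfield-to-acoustic-property mapping constants
#'
#' Endpoints and exponents of the piecewise-linear pseudo-porosity mapping
#' used by [hu_to_properties()]. The published literature maps CT attenuation
#' to bone acoustic properties through the apparent porosity
#' `phi = 1 - HU / hu_max`; the specific endpoint constants vary between
#' groups and scanners, so every one is exposed here. Defaults: cortical bone
#' 2100 kg/m^3 and 2800 m/s, bone attenuation between 23 Np/m (dense
#' cortical) and 70 Np/m (most porous trabecular) at the 200 kHz reference
#' frequency, porosity exponent `beta = 0.5`.
#'
#' @param hu_soft_threshold Below this HU the voxel takes soft-tissue
#'   constants.
#' @param hu_max HU treated as fully mineralized cortical bone.
#' @param rho_soft_kg_m3,c_soft_m_s,alpha_soft_np_m Soft-tissue (water-like)
#'   endpoints.
#' @param rho_bone_kg_m3,c_bone_m_s Cortical-bone endpoints.
#' @param alpha_min_np_m,alpha_max_np_m Bone attenuation at porosity 0 and 1.
#' @param beta Porosity exponent in the attenuation interpolation.
#' @return A list of class `property_mapping`.
#' @export
property_mapping <- function(hu_soft_threshold = 300, hu_max = 2000,
                             rho_soft_kg_m3 = 997, c_soft_m_s = 1494,
                             alpha_soft_np_m = 0.025,
                             rho_bone_kg_m3 = 2100, c_bone_m_s = 2800,
                             alpha_min_np_m = 23, alpha_max_np_m = 70,
                             beta = 0.5) {
  if (hu_soft_threshold >= hu_max) {
    stop("mapping endpoints not ordered: hu_soft_threshold must be below ",
         "hu_max", call. = FALSE)
  }
  if (c_bone_m_s <= c_soft_m_s || rho_bone_kg_m3 <= rho_soft_kg_m3) {
    stop("bone endpoints must exceed soft-tissue endpoints", call. = FALSE)
  }
  structure(as.list(environment()), class = "property_mapping")
}

#' Map calibrated HU values to acoustic properties
#'
#' Piecewise mapping on the pseudo-porosity `phi = 1 - HU/hu_max`:
#' * `HU <= hu_soft_threshold` -> soft-tissue constants;
#' * `HU >= hu_max` -> cortical endpoints;
#' * in between -> `rho = phi rho_soft + (1-phi) rho_bone`,
#'   `c = c_soft + (1-phi)(c_bone - c_soft)`,
#'   `alpha = alpha_min + phi^beta (alpha_max - alpha_min)`.
#'
#' Density and sound speed are monotone non-decreasing in HU; attenuation
#' peaks in porous (trabecular) bone, as scattering-dominated bone loss does.
#'
#' @param hu Numeric vector or array of calibrated HU values.
#' @param mapping A [property_mapping()].
#' @return A list of `density_kg_m3`, `sound_speed_m_s`, `attenuation_np_m`
#'   with the shape of `hu`.
#' @export
hu_to_properties <- function(hu, mapping = property_mapping()) {
  stopifnot(inherits(mapping, "property_mapping"))
  m <- mapping
  hu_c <- pmin(pmax(hu, m$hu_soft_threshold), m$hu_max)
  phi <- 1 - hu_c / m$hu_max
  rho <- phi * m$rho_soft_kg_m3 + (1 - phi) * m$rho_bone_kg_m3
  cs <- m$c_soft_m_s + (1 - phi) * (m$c_bone_m_s - m$c_soft_m_s)
  al <- m$alpha_min_np_m + phi^m$beta * (m$alpha_max_np_m - m$alpha_min_np_m)
  soft <- hu <= m$hu_soft_threshold
  rho[soft] <- m$rho_soft_kg_m3
  cs[soft] <- m$c_soft_m_s
  al[soft] <- m$alpha_soft_np_m
  keep_dim <- function(x) { dim(x) <- dim(hu); x }
  list(density_kg_m3 = keep_dim(rho), sound_speed_m_s = keep_dim(cs),
       attenuation_np_m = keep_dim(al))
}

# 6-neighbour flood fill from the volume boundary through `open` voxels;
# returns logical array of voxels reachable from outside
flood_from_boundary <- function(open) {
  d <- dim(open)
  reach <- array(FALSE, d)
  edge <- array(FALSE, d)
  edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE
  edge[, , c(1, d[3])] <- TRUE
  reach <- open & edge
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & open
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

#' Build a material grid from a calibrated CT volume
#'
#' Maps every voxel to density, sound speed and attenuation via
#' [hu_to_properties()] and labels voxels as exterior water/soft (0), brain
#' (1, interior soft tissue enclosed by the skull shell) or skull (2, above
#' the soft-tissue HU threshold). The brain/water distinction is topological:
#' soft-tissue voxels not connected to the volume boundary through soft
#' tissue are interior, hence brain.
#'
#' @param ct A calibrated [vox_volume()] of HU values.
#' @param mapping A [property_mapping()].
#' @return An object of class `material_grid` with array fields
#'   `density_kg_m3`, `sound_speed_m_s`, `attenuation_np_m`, integer `label`,
#'   plus `spacing_m` and `origin_m`.
#' @export
build_material_grid <- function(ct, mapping = property_mapping()) {
  stopifnot(inherits(ct, "vox_volume"))
  props <- hu_to_properties(ct$data, mapping)
  skull <- ct$data > mapping$hu_soft_threshold
  outside <- flood_from_boundary(!skull)
  label <- array(0L, dim(ct$data))
  label[!skull & !outside] <- 1L
  label[skull] <- 2L
  structure(c(props, list(label = label, spacing_m = ct$spacing_m,
                          origin_m = ct$origin_m, mapping = mapping)),
            class = "material_grid")
}

#' Homogeneous material grid
#'
#' A uniform medium (water by default) on a given grid: the free-field
#' configuration of the FDTD solver.
#'
#' @param grid A [vox_volume()] template.
#' @param medium A [medium_constants()].
#' @param attenuation_np_m Uniform amplitude attenuation, Np/m.
#' @return A `material_grid`.
#' @export
homogeneous_material_grid <- function(grid, medium = medium_constants(),
                                      attenuation_np_m = 0) {
  stopifnot(inherits(grid, "vox_volume"))
  d <- dim(grid$data)
  structure(list(
    density_kg_m3 = array(medium$density_kg_m3, d),
    sound_speed_m_s = array(medium$sound_speed_m_s, d),
    attenuation_np_m = array(attenuation_np_m, d),
    label = array(0L, d), spacing_m = grid$spacing_m,
    origin_m = grid$origin_m, mapping = NULL), class = "material_grid")
}

#' @export
print.material_grid <- function(x, ...) {
  d <- dim(x$density_kg_m3)
  cat("<material_grid> ", paste(d, collapse = " x "), " voxels @ ",
      x$spacing_m * 1e3, " mm\n", sep = "")
  cat("  labels: water/soft ", sum(x$label == 0L), ", brain ",
      sum(x$label == 1L), ", skull ", sum(x$label == 2L), "\n", sep = "")
  cat("  c range: ", paste(signif(range(x$sound_speed_m_s), 5),
                           collapse = " .. "), " m/s\n", sep = "")
  invisible(x)
}
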