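#' Rat-skull CT phantom specification
#'
#' Geometry and texture of the synthetic micro-CT phantom: an ellipsoidal
#' bone shell (elevated, noisy HU) around a soft-tissue interior, air
#' outside, and a cylindrical water calibration tube alongside the skull.
#' Default outer semi-axes 8 x 10 x 7 mm with a 0.9 mm shell give an interior
#' cavity of roughly 14 x 18 x 12 mm — rat scale, within a couple of
#' wavelengths at 200 kHz, so mid-cavity reverberation is geometrically
#' plausible.
#'
#' @param outer_semi_axes_mm Outer shell semi-axes (x, y, z), mm.
#' @param shell_thickness_mm Bone shell thickness, mm.
#' @param shell_hu_mean,shell_hu_sd Gaussian HU texture of the shell.
#' @param interior_hu Soft-tissue interior HU.
#' @param air_hu HU outside the skull and tube.
#' @param noise_hu_sd Global additive HU noise.
#' @param offset_hu Uncalibrated scanner offset applied to the whole volume.
#' @param tube_radius_mm,tube_centre_mm Water-tube radius and (x, y) centre
#'   (the tube runs along z), mm.
#' @param spacing_um Isotropic voxel spacing, micrometres.
#' @param margin_mm Padding between shell and volume edge, mm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semi_axes_mm = c(8, 10, 7),
                         shell_thickness_mm = 0.9,
                         shell_hu_mean = 1600, shell_hu_sd = 150,
                         interior_hu = 40, air_hu = -1000,
                         noise_hu_sd = 15, offset_hu = 0,
                         tube_radius_mm = 1.5,
                         tube_centre_mm = c(-13, 0),
                         spacing_um = 250, margin_mm = 4) {
  if (shell_thickness_mm >= min(outer_semi_axes_mm)) {
    stop("shell thickness must be smaller than the smallest semi-axis",
         call. = FALSE)
  }
  if (spacing_um <= 0) stop("spacing must be positive", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate a synthetic skull CT phantom
#'
#' Deterministic (seeded) voxelization of a [phantom_spec()]: ellipsoidal
#' bone shell with Gaussian HU texture, soft-tissue interior, air outside,
#' and a water tube at HU ~ 0 for calibration. The volume is centred on the
#' skull; a ground-truth label array (0 air, 1 interior soft tissue, 2 bone
#' shell, 3 water tube) is returned alongside.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer RNG seed.
#' @return A list with `ct` (a [vox_volume()] in uncalibrated HU), `labels`
#'   (integer array), `water_roi` (logical array), and `spec`.
#' @export
make_phantom_ct <- function(spec = phantom_spec(), seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  sp <- spec$spacing_um * 1e-6
  semi <- spec$outer_semi_axes_mm * 1e-3
  th <- spec$shell_thickness_mm * 1e-3
  tube_r <- spec$tube_radius_mm * 1e-3
  tube_c <- spec$tube_centre_mm * 1e-3
  margin <- spec$margin_mm * 1e-3
  xmin <- min(-semi[1], tube_c[1] - tube_r) - margin
  xmax <- max(semi[1], tube_c[1] + tube_r) + margin
  ymin <- min(-semi[2], tube_c[2] - tube_r) - margin
  ymax <- max(semi[2], tube_c[2] + tube_r) + margin
  zlim <- semi[3] + margin
  xs <- seq(xmin, xmax, by = sp)
  ys <- seq(ymin, ymax, by = sp)
  zs <- seq(-zlim, zlim, by = sp)
  d <- c(length(xs), length(ys), length(zs))
  gx <- array(xs, d)
  gy <- array(rep(ys, each = d[1]), d)
  gz <- array(rep(zs, each = d[1] * d[2]), d)
  r_out <- (gx / semi[1])^2 + (gy / semi[2])^2 + (gz / semi[3])^2
  si <- semi - th
  r_in <- (gx / si[1])^2 + (gy / si[2])^2 + (gz / si[3])^2
  shell <- r_out <= 1 & r_in > 1
  interior <- r_in <= 1
  tube <- (gx - tube_c[1])^2 + (gy - tube_c[2])^2 <= tube_r^2
  tube <- tube & !shell & !interior
  labels <- array(0L, d)
  labels[interior] <- 1L
  labels[shell] <- 2L
  labels[tube] <- 3L
  hu <- array(spec$air_hu, d)
  hu[interior] <- spec$interior_hu
  hu[tube] <- 0
  hu[shell] <- stats::rnorm(sum(shell), spec$shell_hu_mean, spec$shell_hu_sd)
  hu <- hu + stats::rnorm(length(hu), 0, spec$noise_hu_sd) + spec$offset_hu
  origin <- c(xs[1], ys[1], zs[1])
  list(ct = vox_volume(hu, sp, origin, unit = "HU"),
       labels = labels, water_roi = tube, spec = spec)
}

#' Fluorescence section-set specification
#'
#' Controls the synthetic five-section fluorescence stack: per-section target
#' uptake fractions for each tracer, brain-ellipse geometry, background level
#' and noise, and whether tracer deposits are placed peri-ventricularly
#' (mirroring where CSF tracers concentrate) or scattered.
#'
#' @param uptake One row per section (offsets -2..+2 mm): a data frame /
#'   matrix with one column per tracer of target uptake fractions in
#'   `[0, 1]`.
#' @param background_level Background fluorescence inside the brain (0-255).
#' @param noise_sd Additive Gaussian noise, grey levels.
#' @param signal_level Intensity of tracer deposits (0-255).
#' @param brain_semi_axes_px Brain-ellipse semi-axes (rows, cols), px.
#' @param image_dim Image dimensions (rows, cols).
#' @param periventricular Place deposits around two ventricle-like seed
#'   points near the brain centre (`TRUE`) or around random seeds.
#' @return A list of class `section_set_spec`.
#' @export
section_set_spec <- function(
    uptake = data.frame(oa = c(0.10, 0.14, 0.30, 0.14, 0.10),
                        fitc_d = c(0.005, 0.008, 0.01, 0.008, 0.005)),
    background_level = 60, noise_sd = 4, signal_level = 220,
    brain_semi_axes_px = c(70, 95), image_dim = c(180, 240),
    periventricular = TRUE) {
  uptake <- as.data.frame(uptake)
  if (nrow(uptake) != 5) stop("uptake needs 5 sections", call. = FALSE)
  if (any(uptake < 0 | uptake > 1)) stop("uptake fractions must be in [0,1]",
                                         call. = FALSE)
  structure(as.list(environment()), class = "section_set_spec")
}

#' Generate a synthetic fluorescence section set
#'
#' Builds 5 two-channel section images at offsets -2..+2 mm from the
#' sonication plane. Each channel is a background-fluorescent brain ellipse
#' plus tracer deposits grown from seed points (peri-ventricular by default)
#' to hit the target uptake fraction exactly at zero noise, then additive
#' Gaussian noise. Ground-truth deposit masks and the brain mask are
#' attached to every section.
#'
#' @param spec A [section_set_spec()].
#' @param seed Integer RNG seed.
#' @return A list of 5 sections, each with `channels` (named list of
#'   matrices), `brain_mask`, `truth_masks`, `section_offset_mm`, plus an
#'   attached `truth` tibble of target fractions.
#' @export
make_section_set <- function(spec = section_set_spec(), seed = 1) {
  stopifnot(inherits(spec, "section_set_spec"))
  set.seed(seed)
  d <- spec$image_dim
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  c0 <- (d + 1) / 2
  brain <- ((rows - c0[1]) / spec$brain_semi_axes_px[1])^2 +
    ((cols - c0[2]) / spec$brain_semi_axes_px[2])^2 <= 1
  n_brain <- sum(brain)
  offsets <- c(-2, -1, 0, 1, 2)
  tracers <- names(spec$uptake)
  truth <- list()
  sections <- lapply(seq_along(offsets), function(si) {
    channels <- list(); masks <- list()
    for (tr in tracers) {
      frac <- spec$uptake[si, tr]
      n_target <- round(frac * n_brain)
      mask <- matrix(FALSE, d[1], d[2])
      if (n_target > 0) {
        seeds <- if (spec$periventricular) {
          rbind(c0 + c(-0.12, -0.18) * spec$brain_semi_axes_px,
                c0 + c(-0.12, 0.18) * spec$brain_semi_axes_px)
        } else {
          cbind(stats::runif(2, c0[1] - 30, c0[1] + 30),
                stats::runif(2, c0[2] - 40, c0[2] + 40))
        }
        dist2 <- pmin(
          (rows - seeds[1, 1])^2 + (cols - seeds[1, 2])^2,
          (rows - seeds[2, 1])^2 + (cols - seeds[2, 2])^2)
        dist2[!brain] <- Inf
        ord <- order(dist2)[seq_len(n_target)]   # exact pixel count
        mask[ord] <- TRUE
      }
      img <- matrix(0, d[1], d[2])
      img[brain] <- spec$background_level
      img[mask] <- spec$signal_level
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
      img <- pmin(pmax(img, 0), 255)
      channels[[tr]] <- img
      masks[[tr]] <- mask
      truth[[length(truth) + 1]] <<- tibble::tibble(
        section_offset_mm = offsets[si], tracer = tr,
        target_fraction = frac, n_px = n_target)
    }
    list(channels = channels, brain_mask = brain, truth_masks = masks,
         section_offset_mm = offsets[si])
  })
  attr(sections, "truth") <- dplyr::bind_rows(truth)
  attr(sections, "spec") <- spec
  sections
}

#' Generate a synthetic foam dye-infiltration scan pair
#'
#' A front view (dark disk of the given diameter on textured light foam) and
#' a mid-section view (dark half-ellipse of the given depth descending from
#' the sonicated face along the row axis), both 8-bit grayscale with ground
#' truth attached.
#'
#' @param diameter_mm Inlet diameter of the dye mark.
#' @param depth_mm Infiltration depth.
#' @param mm_per_px Pixel size, mm.
#' @param seed Integer RNG seed.
#' @param foam_level,dye_level Background and dye grey levels.
#' @param noise_sd Foam texture noise, grey levels.
#' @param image_mm Square image side, mm.
#' @return A list with `front`, `section` (matrices), `mm_per_px`, `truth`.
#' @export
make_foam_scan <- function(diameter_mm = 16.5, depth_mm = 6.1,
                           mm_per_px = 0.25, seed = 1,
                           foam_level = 225, dye_level = 80,
                           noise_sd = 8, image_mm = 30) {
  if (diameter_mm <= 0 || depth_mm <= 0) {
    stop("diameter and depth must be positive", call. = FALSE)
  }
  if (diameter_mm >= image_mm || depth_mm >= image_mm) {
    stop("dye mark exceeds the image", call. = FALSE)
  }
  set.seed(seed)
  n <- round(image_mm / mm_per_px)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  c0 <- (n + 1) / 2
  r_px <- diameter_mm / 2 / mm_per_px
  blob <- function(mask) {
    img <- matrix(foam_level, n, n) + stats::rnorm(n * n, 0, noise_sd)
    img[mask] <- dye_level + stats::rnorm(sum(mask), 0, noise_sd / 2)
    pmin(pmax(img, 0), 255)
  }
  front_mask <- (rows - c0)^2 + (cols - c0)^2 <= r_px^2
  # section: half-ellipse from the sonicated face (top rows), depth along rows
  face_row <- round(0.15 * n)
  dep_px <- depth_mm / mm_per_px
  # continuous dye region starts at the top EDGE of the face-row pixel, so
  # pixel centres sit at (rows - face_row + 0.5) below the face
  sec_mask <- rows >= face_row &
    ((rows - face_row + 0.5) / dep_px)^2 + ((cols - c0) / r_px)^2 <= 1
  list(front = blob(front_mask), section = blob(sec_mask),
       mm_per_px = mm_per_px,
       truth = tibble::tibble(diameter_mm = diameter_mm, depth_mm = depth_mm,
                              front_px = sum(front_mask),
                              section_px = sum(sec_mask)))
}

#' Assemble the transcranial phantom simulation domain
#'
#' Embeds a synthetic skull phantom in a water-filled FDTD domain in the
#' arrangement used for in-vivo sonication: the beam travels along the
#' shortest (height) axis of the skull, entering through the cap, with the
#' geometric focus placed a configurable depth below the outer skull
#' surface (default 1 mm, the targeting depth from the top of the head).
#' The transducer sits clear of the absorbing boundary layer.
#'
#' @param spec A [phantom_spec()]; its CT is generated at `ct_spacing_um` and
#'   resampled to the simulation spacing.
#' @param seed RNG seed for the phantom.
#' @param spacing_m Simulation grid spacing (default 0.5 mm).
#' @param ct_spacing_um Native phantom CT spacing (default equal to the
#'   simulation spacing; set finer to exercise the resampling step).
#' @param focus_depth_m Depth of the geometric focus below the outer skull
#'   surface along the beam.
#' @param lateral_halfwidth_m Lateral half-extent of the domain.
#' @param mapping A [property_mapping()].
#' @return A list: `mat` (`material_grid`), `geom`
#'   ([transducer_geometry()] with axis +x), `ct` (embedded calibrated HU
#'   volume), `phantom` (the raw generator output).
#' @export
phantom_domain <- function(spec = phantom_spec(), seed = 1,
                           spacing_m = 0.5e-3, ct_spacing_um = NULL,
                           focus_depth_m = 1e-3,
                           lateral_halfwidth_m = 0.025,
                           mapping = property_mapping()) {
  if (is.null(ct_spacing_um)) ct_spacing_um <- spacing_m * 1e6
  spec$spacing_um <- ct_spacing_um
  ph <- make_phantom_ct(spec, seed = seed)
  ct <- calibrate_hu(ph$ct, ph$water_roi)
  sub <- ct$data
  sub[sub < -300] <- 0                     # exterior air -> coupling water
  if (ct_spacing_um * 1e-6 < spacing_m - 1e-12) {
    ctv <- resample_isotropic(vox_volume(sub, ct_spacing_um * 1e-6,
                                         ct$origin_m, "HU"), spacing_m)
    sub <- ctv$data
  }
  # beam along the z semi-axis of the phantom: rotate z -> x
  sub <- aperm(sub, c(3, 2, 1))
  geom <- transducer_geometry(position_m = c(0, 0, 0), axis = c(1, 0, 0))
  lam_sponge <- 1.2 * 7.5e-3               # clearance for the sponge layer
  apex_x <- lam_sponge + 1.5e-3
  focus_x <- apex_x + geom$curvature_radius_m
  semi_beam <- spec$outer_semi_axes_mm[3] * 1e-3
  centre_x <- focus_x - focus_depth_m + semi_beam
  x_max <- centre_x + semi_beam + 4e-3 + lam_sponge
  nx <- ceiling(x_max / spacing_m) + 1
  nyz <- 2 * round(lateral_halfwidth_m / spacing_m) + 1
  org <- c(0, -lateral_halfwidth_m, -lateral_halfwidth_m)
  hu <- array(0, c(nx, nyz, nyz))
  dph <- dim(sub)
  oph <- ct$origin_m[c(3, 2, 1)]           # phantom origin after rotation
  off <- round((c(centre_x, 0, 0) + oph - org) / spacing_m)
  ix <- off[1] + seq_len(dph[1]); iy <- off[2] + seq_len(dph[2])
  iz <- off[3] + seq_len(dph[3])
  if (min(ix, iy, iz) < 1 || max(ix) > nx || max(iy) > nyz || max(iz) > nyz) {
    stop("phantom does not fit in the simulation domain", call. = FALSE)
  }
  hu[ix, iy, iz] <- sub
  geom$position_m <- c(apex_x, 0, 0)
  list(mat = build_material_grid(vox_volume(hu, spacing_m, org, "HU"), mapping),
       geom = geom,
       ct = vox_volume(hu, spacing_m, org, "HU"),
       phantom = ph)
}
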