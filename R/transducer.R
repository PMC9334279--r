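#' Focused bowl transducer geometry
#'
#' Single-element spherical-cap (bowl) source, described by its aperture
#' diameter and radius of curvature. `position` is the apex (deepest point of
#' the bowl); `axis` is the unit propagation direction, so the geometric centre
#' of curvature lies at `position + curvature_radius * axis`. The exit plane is
#' the plane through the bowl rim, a cap depth
#' `h = R - sqrt(R^2 - (D/2)^2)` in front of the apex.
#'
#' Defaults are a 28 mm aperture with 22 mm radius of curvature, a compact
#' low-frequency bowl for small-animal transcranial work.
#'
#' @param aperture_diameter_m Aperture (rim) diameter D in metres.
#' @param curvature_radius_m Radius of curvature R in metres; requires
#'   `D <= 2 R`.
#' @param position_m Apex position, length-3, metres.
#' @param axis Propagation direction; normalized internally.
#' @return An object of class `transducer_geometry`.
#' @export
transducer_geometry <- function(aperture_diameter_m = 0.028,
                                curvature_radius_m = 0.022,
                                position_m = c(0, 0, 0),
                                axis = c(1, 0, 0)) {
  if (aperture_diameter_m <= 0 || curvature_radius_m <= 0) {
    stop("aperture and curvature radius must be positive", call. = FALSE)
  }
  if (aperture_diameter_m > 2 * curvature_radius_m + 1e-12) {
    stop("aperture diameter cannot exceed twice the curvature radius",
         call. = FALSE)
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a nonzero vector", call. = FALSE)
  structure(list(aperture_diameter_m = aperture_diameter_m,
                 curvature_radius_m = curvature_radius_m,
                 position_m = as.numeric(position_m),
                 axis = as.numeric(axis) / nrm),
            class = "transducer_geometry")
}

#' Cap depth and radiating area of a bowl
#'
#' Closed-form spherical-cap geometry: depth `h = R - sqrt(R^2 - (D/2)^2)`
#' and area `2 pi R h`.
#'
#' @param geom A [transducer_geometry()].
#' @return Named list with `cap_depth_m` and `cap_area_m2`.
#' @export
bowl_cap_geometry <- function(geom) {
  stopifnot(inherits(geom, "transducer_geometry"))
  r <- geom$curvature_radius_m
  a <- geom$aperture_diameter_m / 2
  h <- r - sqrt(r^2 - a^2)
  list(cap_depth_m = h, cap_area_m2 = 2 * pi * r * h)
}

# orthonormal basis (e1, e2) perpendicular to a unit axis
perp_basis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Discretize the bowl surface into uniform-area patches
#'
#' Covers the spherical cap with `n` point-like patches of equal area using a
#' spiral (Fibonacci) layout uniform in `cos(theta)`, so patch areas sum to the
#' closed-form cap area exactly. The patch count is chosen so the patch linear
#' size is at most `lambda / patches_per_wavelength`.
#'
#' @param geom A [transducer_geometry()].
#' @param wavelength_m Carrier wavelength in the load medium, metres.
#' @param patches_per_wavelength Minimum patches per wavelength (>= 4).
#' @return A tibble with patch centres (`x`,`y`,`z`, m), unit inward normals
#'   (`nx`,`ny`,`nz`) and `area_m2`.
#' @export
discretize_bowl <- function(geom, wavelength_m, patches_per_wavelength = 8) {
  stopifnot(inherits(geom, "transducer_geometry"))
  if (patches_per_wavelength < 4) {
    stop("patches_per_wavelength must be at least 4", call. = FALSE)
  }
  cap <- bowl_cap_geometry(geom)
  patch_size <- wavelength_m / patches_per_wavelength
  n <- max(64L, ceiling(cap$cap_area_m2 / patch_size^2))
  r <- geom$curvature_radius_m
  theta_max <- asin(geom$aperture_diameter_m / (2 * r))
  # uniform in cos(theta) over [cos(theta_max), 1] -> equal-area bands
  u <- (seq_len(n) - 0.5) / n
  cth <- 1 - u * (1 - cos(theta_max))
  sth <- sqrt(pmax(0, 1 - cth^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  b <- perp_basis(geom$axis)
  centre <- geom$position_m + r * geom$axis   # centre of curvature
  # surface point = centre - R * (cth * axis + sth * (cos phi e1 + sin phi e2))
  dirx <- cth * geom$axis[1] + sth * (cos(phi) * b$e1[1] + sin(phi) * b$e2[1])
  diry <- cth * geom$axis[2] + sth * (cos(phi) * b$e1[2] + sin(phi) * b$e2[2])
  dirz <- cth * geom$axis[3] + sth * (cos(phi) * b$e1[3] + sin(phi) * b$e2[3])
  tibble::tibble(
    x = centre[1] - r * dirx, y = centre[2] - r * diry,
    z = centre[3] - r * dirz,
    nx = dirx, ny = diry, nz = dirz,        # inward: toward the focus
    area_m2 = cap$cap_area_m2 / n)
}

#' Free-field pressure of the bowl source (Rayleigh-Sommerfeld)
#'
#' Harmonic steady-state pressure amplitude of the uniformly vibrating bowl in
#' a homogeneous lossless medium, by complex summation of simple sources over
#' the discretized cap:
#' \deqn{p(r) = \frac{i \omega \rho u_0}{2\pi} \sum_j A_j
#'       \frac{e^{-i k r_j}}{r_j}}{p(r) = (i w rho u0 / 2pi) sum_j A_j exp(-i k r_j)/r_j}
#' The result is linear in the surface velocity `u0`; fields are routinely
#' rescaled afterwards to a target focal intensity.
#'
#' Serves both as the standalone free-field simulator and as the reference
#' oracle for the FDTD solver.
#'
#' @param geom A [transducer_geometry()].
#' @param f_hz Drive frequency, Hz.
#' @param medium A [medium_constants()].
#' @param grid A [vox_volume()] template giving dims, spacing and origin of the
#'   output field (its data are ignored).
#' @param u0_m_s Uniform normal surface velocity amplitude, m/s.
#' @param patches_per_wavelength Passed to [discretize_bowl()].
#' @return A [vox_volume()] of pressure amplitude (Pa, unit "Pa").
#' @export
freefield_pressure <- function(geom, f_hz, medium, grid, u0_m_s = 1,
                               patches_per_wavelength = 8) {
  stopifnot(inherits(grid, "vox_volume"))
  lam <- wavelength(f_hz, medium$sound_speed_m_s)
  if (grid$spacing_m > lam / 6 + 1e-12) {
    stop("grid spacing must be at most lambda/6 (",
         signif(lam / 6 * 1e3, 4), " mm)", call. = FALSE)
  }
  patches <- discretize_bowl(geom, lam, patches_per_wavelength)
  k <- 2 * pi / lam
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
  zs <- axis_coords(grid, 3)
  d <- dim(grid$data)
  gx <- array(xs, d); gy <- array(rep(ys, each = d[1]), d)
  gz <- array(rep(zs, each = d[1] * d[2]), d)
  acc <- array(complex(real = 0), d)
  rmin <- sqrt(patches$area_m2[1] / pi) / 2   # regularization near the surface
  for (j in seq_len(nrow(patches))) {
    r <- sqrt((gx - patches$x[j])^2 + (gy - patches$y[j])^2 +
              (gz - patches$z[j])^2)
    r <- pmax(r, rmin)
    acc <- acc + patches$area_m2[j] * exp(-1i * k * r) / r
  }
  omega <- 2 * pi * f_hz
  p <- Mod(1i * omega * medium$density_kg_m3 * u0_m_s / (2 * pi) * acc)
  vox_volume(p, grid$spacing_m, grid$origin_m, unit = "Pa")
}

#' Empty field grid
#'
#' Convenience constructor for the grid template consumed by
#' [freefield_pressure()] and the FDTD solver.
#'
#' @param dims Length-3 integer voxel counts.
#' @param spacing_m Isotropic spacing, metres.
#' @param origin_m World coordinate of voxel (1,1,1), metres.
#' @return A zero-filled [vox_volume()].
#' @export
make_grid <- function(dims, spacing_m, origin_m = c(0, 0, 0)) {
  vox_volume(array(0, dim = dims), spacing_m, origin_m)
}
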