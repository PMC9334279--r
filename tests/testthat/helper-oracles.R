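# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: quadrature instead of patch summation,
# closed forms instead of grid solvers.

# on-axis pressure of a focused bowl by 1D ring quadrature over the cap
axial_pressure_oracle <- function(x, geom, f_hz, medium, u0 = 1, nq = 4000) {
  R <- geom$curvature_radius_m
  a <- geom$aperture_diameter_m / 2
  thmax <- asin(a / R)
  k <- 2 * pi * f_hz / medium$sound_speed_m_s
  th <- (seq_len(nq) - 0.5) / nq * thmax
  dth <- thmax / nq
  x0 <- sum(geom$position_m * geom$axis)
  xr <- x0 + R * (1 - cos(th))      # ring axial positions
  rr <- R * sin(th)                 # ring radii
  vapply(x, function(xx) {
    r <- sqrt((xx - xr)^2 + rr^2)
    dS <- 2 * pi * R^2 * sin(th) * dth
    Mod(1i * 2 * pi * f_hz * medium$density_kg_m3 * u0 / (2 * pi) *
          sum(dS * exp(-1i * k * r) / r))
  }, numeric(1))
}

# centre temperature elevation of an isotropic Gaussian heat source in an
# unbounded conducting medium (time-dependent Green's-function convolution)
gaussian_dT_centre <- function(t, q0, sigma, k_cond, rho, c_t) {
  kappa <- k_cond / (rho * c_t)
  q0 * sigma^2 / k_cond * (1 - sigma / sqrt(sigma^2 + 2 * kappa * t))
}

# centre elevation with a perfusion sink (screened Poisson closed form)
gaussian_dT_perfused <- function(q0, sigma, k_cond, wb_cb) {
  a <- wb_cb / k_cond
  x <- sigma * sqrt(a / 2)
  q0 * sigma^2 / k_cond *
    (1 - sqrt(pi / 2) * sigma * sqrt(a) * exp(x^2) * pracma::erfc(x))
}

# standard water medium used throughout (24 degrees C bath)
water24 <- function() medium_constants(997, 1494)

# small free-field material grid wide enough that the beam cone clears the
# absorbing layer
freefield_setup <- function(dx = 0.5e-3, nx = 90, nyz = 101,
                            apex_x = 0.006) {
  grid <- make_grid(c(nx, nyz, nyz), dx,
                    c(0, -((nyz - 1) / 2) * dx, -((nyz - 1) / 2) * dx))
  list(grid = grid,
       mat = homogeneous_material_grid(grid, water24()),
       geom = transducer_geometry(position_m = c(apex_x, 0, 0),
                                  axis = c(1, 0, 0)))
}
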