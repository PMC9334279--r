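test_that("spherical-cap geometry matches the closed form", {
  g <- transducer_geometry()      # 28 mm aperture, 22 mm curvature
  cap <- bowl_cap_geometry(g)
  h_ana <- 0.022 - sqrt(0.022^2 - 0.014^2)
  expect_equal(cap$cap_depth_m, h_ana)
  expect_equal(cap$cap_area_m2, 2 * pi * 0.022 * h_ana)
  # hemisphere limit: D = 2R -> h = R
  hemi <- bowl_cap_geometry(transducer_geometry(0.044, 0.022))
  expect_equal(hemi$cap_depth_m, 0.022)
  expect_error(transducer_geometry(0.05, 0.022), "exceed")
  expect_error(transducer_geometry(axis = c(0, 0, 0)), "nonzero")
})

test_that("bowl discretization covers the cap with uniform-area patches", {
  g <- transducer_geometry()
  p <- discretize_bowl(g, wavelength_m = 7.5e-3, patches_per_wavelength = 8)
  cap <- bowl_cap_geometry(g)
  expect_lt(abs(sum(p$area_m2) - cap$cap_area_m2) / cap$cap_area_m2, 0.005)
  expect_equal(length(unique(p$area_m2)), 1L)   # uniform areas
  # every patch centre lies on the sphere of curvature
  cen <- g$position_m + g$curvature_radius_m * g$axis
  r <- sqrt((p$x - cen[1])^2 + (p$y - cen[2])^2 + (p$z - cen[3])^2)
  expect_true(all(abs(r - g$curvature_radius_m) < 1e-12))
  # normals point toward the centre of curvature
  expect_true(all(abs((cen[1] - p$x) / g$curvature_radius_m - p$nx) < 1e-12))
  expect_error(discretize_bowl(g, 7.5e-3, patches_per_wavelength = 2),
               "at least 4")
})

test_that("free field is linear, axially located and oracle-consistent", {
  med <- water24()
  g <- transducer_geometry(position_m = c(0.002, 0, 0), axis = c(1, 0, 0))
  # on-axis line through the focus
  line <- make_grid(c(90, 1, 1), 0.5e-3, c(0.004, 0, 0))
  pf <- freefield_pressure(g, 200e3, med, line)
  ora <- axial_pressure_oracle(axis_coords(line, 1), g, 200e3, med)
  expect_lt(max(abs(pf$data - ora)) / max(ora), 0.02)
  # axial peak between the exit plane and the centre of curvature
  xpk <- axis_coords(line, 1)[which.max(pf$data)]
  cap <- bowl_cap_geometry(g)
  expect_gt(xpk, g$position_m[1] + cap$cap_depth_m)
  expect_lt(xpk, g$position_m[1] + g$curvature_radius_m)
  # linearity in the drive
  pf2 <- freefield_pressure(g, 200e3, med, line, u0_m_s = 2)
  expect_equal(pf2$data, 2 * pf$data, tolerance = 1e-12)
  # patch-refinement convergence at the focus: halving patch size < 1%
  fp <- make_grid(c(1, 1, 1), 1e-3, c(xpk, 0, 0))
  p8 <- freefield_pressure(g, 200e3, med, fp, patches_per_wavelength = 8)
  p16 <- freefield_pressure(g, 200e3, med, fp, patches_per_wavelength = 16)
  expect_lt(abs(p16$data - p8$data) / p16$data, 0.01)
  expect_error(freefield_pressure(g, 200e3, med,
                                  make_grid(c(10, 1, 1), 2e-3)), "lambda/6")
})

test_that("free field is rotationally symmetric about the beam axis", {
  med <- water24()
  g <- transducer_geometry(position_m = c(0.001, 0, 0), axis = c(1, 0, 0))
  grid <- make_grid(c(30, 21, 21), 1e-3, c(0.008, -0.010, -0.010))
  pf <- freefield_pressure(g, 200e3, med, grid)
  # swapping the two transverse axes must leave the field unchanged up to
  # the (asymmetric) spiral discretization of the cap
  expect_lt(max(abs(pf$data - aperm(pf$data, c(1, 3, 2)))) / max(pf$data),
            0.02)
  # transverse profile symmetric under reflection, same tolerance
  mid <- pf$data[15, , 11]
  expect_lt(max(abs(mid - rev(mid))) / max(pf$data), 0.02)
})

test_that("free-field focus geometry sits in the measured regime", {
  # the ideal uniformly-vibrating cap puts the -6 dB focus near the measured
  # 7 mm x 27 mm at 200 kHz, with the axial peak ~11 mm from the exit plane
  med <- water24()
  g <- transducer_geometry(position_m = c(0.002, 0, 0), axis = c(1, 0, 0))
  grid <- make_grid(c(100, 41, 41), 1e-3, c(0, -0.020, -0.020))
  pf <- freefield_pressure(g, 200e3, med, grid)
  fm <- focus_metrics(pf, g)
  expect_lt(abs(fm$lateral_fwhm_m - 7e-3) / 7e-3, 0.30)
  expect_lt(abs(fm$axial_fwhm_m - 27e-3) / 27e-3, 0.30)
  expect_lt(fm$axial_fw90_m, fm$axial_fwhm_m)
  expect_lt(fm$lateral_fw90_m, fm$lateral_fwhm_m)
  expect_lt(abs(fm$focal_distance_from_exit_plane_m - 11e-3), 3e-3)
})
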