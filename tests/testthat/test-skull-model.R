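test_that("water calibration is an idempotent affine shift", {
  arr <- array(rnorm(8^3, mean = 50, sd = 5), c(8, 8, 8))
  roi <- array(FALSE, c(8, 8, 8)); roi[1:4, , ] <- TRUE
  ct <- vox_volume(arr, 1e-3)
  cal <- calibrate_hu(ct, roi)
  expect_equal(mean(cal$data[roi]), 0)
  expect_equal(calibrate_hu(cal, roi)$data, cal$data)       # idempotent
  # a global offset is removed while relative contrast is preserved
  off <- calibrate_hu(vox_volume(arr + 100, 1e-3), roi)
  expect_equal(off$data, cal$data)
  expect_error(calibrate_hu(ct, array(FALSE, c(8, 8, 8))), "empty")
})

test_that("phantom calibration recovers the water-tube reference", {
  ph <- make_phantom_ct(phantom_spec(spacing_um = 500, offset_hu = 37),
                        seed = 11)
  expect_lt(abs(mean(ph$ct$data[ph$water_roi]) - 37), 2)  # offset present
  cal <- calibrate_hu(ph$ct, ph$water_roi)
  expect_lt(abs(mean(cal$data[ph$water_roi])), 1e-9)
})

test_that("isotropic resampling preserves constants and geometry", {
  arr <- array(7, c(40, 30, 20))
  v <- vox_volume(arr, 0.1e-3)
  r <- resample_isotropic(v, 0.25e-3)
  expect_equal(r$spacing_m, 0.25e-3)
  expect_true(all(abs(r$data - 7) < 1e-12))
  expect_equal(dim(r$data), ceiling(dim(arr) * 0.1 / 0.25))
  # a linear ramp resamples exactly under linear interpolation
  ramp <- vox_volume(array(rep(seq_len(40), 30 * 20), c(40, 30, 20)), 0.1e-3)
  rr <- resample_isotropic(ramp, 0.2e-3)
  xs <- axis_coords(rr, 1)
  expect_equal(rr$data[, 1, 1], 1 + xs / 0.1e-3, tolerance = 1e-12)
  expect_error(resample_isotropic(v, 0.05e-3), "coarsens")
  # the default target gives 30 voxels per wavelength at 200 kHz in water
  expect_equal(wavelength(200e3, 1500) / 0.25e-3, 30)
})

test_that("HU-to-property mapping hits its endpoints and is monotone", {
  m <- property_mapping()
  p0 <- hu_to_properties(0, m)
  expect_equal(p0$density_kg_m3, 997)
  expect_equal(p0$sound_speed_m_s, 1494)
  expect_lt(p0$attenuation_np_m, 0.1)
  pmax <- hu_to_properties(m$hu_max, m)
  expect_equal(pmax$density_kg_m3, 2100)
  expect_equal(pmax$sound_speed_m_s, 2800)
  expect_equal(pmax$attenuation_np_m, m$alpha_min_np_m)
  hu <- seq(0, m$hu_max, by = 10)
  pr <- hu_to_properties(hu, m)
  expect_true(all(diff(pr$density_kg_m3) >= 0))
  expect_true(all(diff(pr$sound_speed_m_s) >= 0))
  expect_true(all(pr$attenuation_np_m > 0))
  # values beyond the cortical endpoint saturate
  expect_equal(hu_to_properties(1e4, m)$sound_speed_m_s, 2800)
  expect_error(property_mapping(hu_soft_threshold = 2500), "ordered")
})

test_that("material grid reproduces the phantom shell geometry", {
  ph <- make_phantom_ct(phantom_spec(spacing_um = 500), seed = 5)
  mat <- build_material_grid(calibrate_hu(ph$ct, ph$water_roi))
  truth <- ph$labels == 2L
  got <- mat$label == 2L
  dice <- 2 * sum(truth & got) / (sum(truth) + sum(got))
  expect_gte(dice, 0.95)
  # interior soft tissue is labelled brain, exterior stays water/soft
  interior <- ph$labels == 1L
  expect_gt(mean(mat$label[interior] == 1L), 0.95)
  expect_true(all(mat$label[ph$labels == 0L] %in% c(0L, 2L)))
  # water voxels carry the water constants exactly
  w <- mat$label == 0L & abs(mat$density_kg_m3 - 997) < 1e-9
  expect_equal(sum(w), sum(mat$label == 0L))
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  v <- vox_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), 0.25e-3, unit = "HU")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$spacing_m, v$spacing_m, tolerance = 1e-6)
  expect_equal(r$data, v$data, tolerance = 1e-6)
  unlink(path)
})
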