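test_that("generators are deterministic under a fixed seed", {
  p1 <- make_phantom_ct(phantom_spec(spacing_um = 500), seed = 3)
  p2 <- make_phantom_ct(phantom_spec(spacing_um = 500), seed = 3)
  expect_identical(p1$ct$data, p2$ct$data)
  s1 <- make_section_set(seed = 3)
  s2 <- make_section_set(seed = 3)
  expect_identical(s1[[1]]$channels$oa, s2[[1]]$channels$oa)
  f1 <- make_foam_scan(seed = 3)
  f2 <- make_foam_scan(seed = 3)
  expect_identical(f1$front, f2$front)
  # different seeds differ
  expect_false(identical(make_foam_scan(seed = 4)$front, f1$front))
})

test_that("phantom shell is a closed surface around the interior", {
  ph <- make_phantom_ct(phantom_spec(spacing_um = 500), seed = 2)
  # interior voxels must not be reachable from the volume boundary without
  # crossing the shell
  outside <- tfusim:::flood_from_boundary(ph$labels != 2L)
  expect_true(all(!outside[ph$labels == 1L]))
  # water tube sits at ~0 HU before calibration (no offset)
  expect_lt(abs(mean(ph$ct$data[ph$water_roi])), 2)
  # shell HU well separated from interior
  expect_gt(mean(ph$ct$data[ph$labels == 2L]),
            mean(ph$ct$data[ph$labels == 1L]) + 500)
  expect_error(phantom_spec(shell_thickness_mm = 10), "semi-axis")
})

test_that("section generator hits target uptake fractions", {
  # zero noise: recovery exact to quantization
  sp0 <- section_set_spec(noise_sd = 0)
  ss0 <- make_section_set(sp0, seed = 1)
  res0 <- quantify_sections(ss0)
  tr0 <- attr(ss0, "truth")
  m0 <- merge(as.data.frame(res0), as.data.frame(tr0),
              by = c("section_offset_mm", "tracer"))
  expect_true(all(abs(m0$percent_uptake - 100 * m0$target_fraction) < 0.05))
  # zero target gives exactly zero recovered uptake
  spz <- section_set_spec(uptake = data.frame(oa = rep(0, 5)), noise_sd = 0)
  ssz <- make_section_set(spz, seed = 1)
  expect_true(all(quantify_sections(ssz)$percent_uptake == 0))
  # ground-truth masks have exactly the requested pixel counts
  ss <- make_section_set(seed = 6)
  tr <- attr(ss, "truth")
  n_mid_oa <- sum(ss[[3]]$truth_masks$oa)
  expect_equal(n_mid_oa, tr$n_px[tr$section_offset_mm == 0 & tr$tracer == "oa"])
  expect_error(section_set_spec(uptake = data.frame(oa = rep(2, 5))),
               "\\[0,1\\]")
})

test_that("foam generator validates its geometry", {
  expect_error(make_foam_scan(diameter_mm = 40, image_mm = 30), "exceeds")
  expect_error(make_foam_scan(diameter_mm = -1), "positive")
  fs <- make_foam_scan(seed = 8)
  expect_true(all(fs$front >= 0 & fs$front <= 255))
  expect_equal(dim(fs$front), dim(fs$section))
})

test_that("phantom domain assembles a water-coupled transcranial setup", {
  dom <- phantom_domain(seed = 2)
  expect_s3_class(dom$mat, "material_grid")
  expect_gt(sum(dom$mat$label == 2L), 0)       # skull present
  expect_gt(sum(dom$mat$label == 1L), 0)       # brain cavity present
  # the geometric focus lies in tissue just inside the proximal shell
  focus <- dom$geom$position_m + dom$geom$curvature_radius_m * dom$geom$axis
  fi <- tfusim:::nearest_voxel(dom$ct, focus)
  expect_true(dom$mat$label[fi[1], fi[2], fi[3]] %in% c(1L, 2L))
  # the transducer apex clears the absorbing margin (about one wavelength)
  expect_gt(dom$geom$position_m[1], 7.5e-3)
})
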