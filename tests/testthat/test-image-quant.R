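test_that("foam segmentation measures synthetic blobs from ground truth", {
  # clean disk: 40 px across at 0.5 mm/px -> 20 mm Feret diameter
  img <- matrix(255, 100, 100)
  rows <- row(img); cols <- col(img)
  img[(rows - 50.5)^2 + (cols - 50.5)^2 <= 19.5^2] <- 80
  r <- foam_infiltration(img, 0.5, "front")
  expect_equal(r$value_mm, 20, tolerance = 0.02)
  # uniform bright image: empty mask, zero with a warning
  expect_warning(r0 <- foam_infiltration(matrix(255, 50, 50), 0.5, "front"),
                 "empty")
  expect_equal(r0$value_mm, 0)
  # bright-polarity scans are supported
  rb <- foam_infiltration(255 - img, 0.5, "front", threshold = 105,
                          polarity = "bright")
  expect_equal(rb$value_mm, 20, tolerance = 0.02)
})

test_that("generated foam scans are recovered within 2%", {
  fs <- make_foam_scan(16.5, 6.1, mm_per_px = 0.25, seed = 3)
  d <- foam_infiltration(fs$front, fs$mm_per_px, "front")
  z <- foam_infiltration(fs$section, fs$mm_per_px, "section")
  expect_lt(abs(d$value_mm - 16.5) / 16.5, 0.02)
  expect_lt(abs(z$value_mm - 6.1) / 6.1, 0.02)
  # zero-noise scans recover exactly to pixel quantization
  fs0 <- make_foam_scan(12, 5, mm_per_px = 0.1, seed = 1, noise_sd = 0)
  d0 <- foam_infiltration(fs0$front, 0.1, "front")
  z0 <- foam_infiltration(fs0$section, 0.1, "section")
  expect_lt(abs(d0$value_mm - 12), 0.1 + 1e-9)
  expect_lt(abs(z0$value_mm - 5), 0.1 + 1e-9)
})

test_that("tracer uptake matches the hand-counted fixture", {
  # 2500-px square brain, background 100, one 10x10 block at 255 -> 4%
  ch <- matrix(0, 70, 70)
  mask <- matrix(FALSE, 70, 70); mask[11:60, 11:60] <- TRUE
  ch[mask] <- 100
  ch[21:30, 21:30] <- 255
  r <- tracer_uptake(list(oa = ch), brain_mask = mask)
  expect_equal(r$percent_uptake, 100 * 100 / 2500)
  # uniform channel: nothing above 1.7 x background
  ru <- tracer_uptake(list(oa = matrix(100, 70, 70) * mask + 0), mask)
  expect_equal(ru$percent_uptake, 0)
  # affine intensity rescaling leaves the result unchanged
  r2 <- tracer_uptake(list(oa = 2 * ch), brain_mask = mask)
  expect_equal(r2$percent_uptake, r$percent_uptake)
  expect_error(tracer_uptake(list(oa = ch), matrix(FALSE, 70, 70)), "empty")
})

test_that("section sets are recovered within half a percentage point", {
  ss <- make_section_set(seed = 4)
  res <- quantify_sections(ss)
  truth <- attr(ss, "truth")
  m <- merge(as.data.frame(res), as.data.frame(truth),
             by = c("section_offset_mm", "tracer"))
  expect_true(all(abs(m$percent_uptake - 100 * m$target_fraction) <= 0.5))
  # the automatic brain mask reproduces the provided-mask result closely
  r_auto <- tracer_uptake(ss[[3]]$channels, brain_mask = NULL)
  r_given <- tracer_uptake(ss[[3]]$channels, ss[[3]]$brain_mask)
  expect_lt(max(abs(r_auto$percent_uptake - r_given$percent_uptake)), 1)
})

test_that("sonicated-plane enhancement is detected where generated", {
  # two synthetic groups: sonicated animals with elevated uptake only at the
  # central section, controls flat - the group difference must be declared
  # at the sonicated plane and not two sections away
  centre_c <- numeric(); centre_v <- numeric()
  edge_c <- numeric(); edge_v <- numeric()
  for (i in 1:6) {
    fus <- quantify_sections(make_section_set(section_set_spec(
      uptake = data.frame(oa = c(0.10, 0.14, 0.30, 0.14, 0.10))),
      seed = 100 + i))
    ctl <- quantify_sections(make_section_set(section_set_spec(
      uptake = data.frame(oa = c(0.10, 0.12, 0.18, 0.12, 0.10))),
      seed = 200 + i))
    centre_v[i] <- fus$percent_uptake[fus$section_offset_mm == 0]
    centre_c[i] <- ctl$percent_uptake[ctl$section_offset_mm == 0]
    edge_v[i] <- fus$percent_uptake[fus$section_offset_mm == 2]
    edge_c[i] <- ctl$percent_uptake[ctl$section_offset_mm == 2]
  }
  df_centre <- data.frame(y = c(centre_c, centre_v),
                          g = rep(c("C", "V"), each = 6))
  df_edge <- data.frame(y = c(edge_c, edge_v),
                        g = rep(c("C", "V"), each = 6))
  expect_lt(glance(group_stats(df_centre, y, g))$p_value, 0.05)
  expect_gt(glance(group_stats(df_edge, y, g))$p_value, 0.05)
})

test_that("one-way ANOVA and Tukey HSD match hand computation", {
  df <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                   g = rep(c("a", "b", "c"), each = 3))
  gs <- group_stats(df, y, g)
  gl <- glance(gs)
  expect_equal(gl$statistic, 3)          # SSB 6 / SSW 6, df (2, 6)
  expect_equal(gl$df_between, 2)
  expect_equal(gl$df_within, 6)
  td <- tidy(gs)
  expect_equal(nrow(td), 3)              # all pairwise contrasts
  expect_equal(unname(sort(td$estimate)), c(1, 1, 2))
  # identical groups: zero between-group variance
  df0 <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(glance(group_stats(df0, y, g))$statistic, 0)
  expect_error(group_stats(df[1:3, ], y, g), "2 groups")
  expect_error(group_stats(data.frame(y = 1:3, g = c("a", "a", "b")), y, g),
               ">= 2 values")
})

test_that("paired t test is two-sided and requires equal lengths", {
  a <- c(0.54, 0.57, 0.52, 0.55, 0.56)
  b <- a + c(0.03, 0.02, 0.04, 0.03, 0.03)
  r <- paired_t(a, b)
  expect_equal(r$statistic, t.test(a, b, paired = TRUE)$statistic,
               ignore_attr = TRUE)
  expect_equal(r$df, 4)
  expect_lt(r$p_value, 0.01)
  expect_error(paired_t(a, b[-1]), "equal length")
})
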