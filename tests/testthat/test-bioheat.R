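test_that("heat source arithmetic and mode equivalence", {
  pt <- pulse_train(2e5, 0.1, 1, 1800, ispta_w_cm2 = 0.65)
  isppa <- vox_volume(array(6.5, c(3, 3, 3)), 1e-3, unit = "W/cm2")
  q_avg <- heat_source(isppa, 0.25, pt, "duty-averaged")
  expect_equal(q_avg$data[1], 2 * 0.25 * 6.5e4 * 0.1)     # 325 W/m3
  q_pk <- heat_source(isppa, 0.25, pt, "pulse-resolved")
  # equal energy per pulse period
  expect_equal(q_pk$data[1] * pt$pd_s, q_avg$data[1] / pt$prf_hz)
  expect_error(heat_source(isppa, -1, pt), "non-negative")
})

test_that("zero source stays at equilibrium; non-negative source warms", {
  lb <- array(1L, c(7, 7, 7))
  tg <- thermal_grid(label = lb, spacing_m = 1e-3)
  q0 <- vox_volume(array(0, c(7, 7, 7)), 1e-3)
  res <- solve_bioheat(q0, tg, bioheat_config(duration_s = 30))
  expect_equal(res$peak_dT, 0)
  expect_true(all(abs(res$T_final$data - 37.5) < 1e-12))
  # maximum principle: temperature never drops below the arterial baseline
  q1 <- vox_volume(array(runif(7^3, 0, 500), c(7, 7, 7)), 1e-3)
  res1 <- solve_bioheat(q1, tg, bioheat_config(duration_s = 60))
  expect_true(min(res1$T_final$data) >= 37.5 - 1e-12)
  expect_gt(res1$peak_dT, 0)
})

test_that("uniform heating follows the lumped perfusion ODE", {
  # uniform q in a uniform perfused block with insulated walls: no gradients,
  # so dT follows (q/wb cb)(1 - exp(-t/tau)), tau = rho c / (wb cb)
  n <- 7L
  tg <- thermal_grid(label = array(1L, c(n, n, n)), spacing_m = 1e-3)
  q <- vox_volume(array(1000, c(n, n, n)), 1e-3)
  res <- solve_bioheat(q, tg, bioheat_config(duration_s = 900,
                                             boundary = "insulated"))
  wbcb <- 8.24 * 3620
  tau <- 1040 * 3600 / wbcb
  expect_lt(abs(res$peak_dT - 1000 / wbcb) / (1000 / wbcb), 0.01)
  t95 <- steady_state_time(res)
  expect_lt(abs(t95 - 3 * tau) / (3 * tau), 0.02)  # -tau ln(0.05) = 2.996 tau
  # linearity in q
  res2 <- solve_bioheat(vox_volume(array(2000, c(n, n, n)), 1e-3), tg,
                        bioheat_config(duration_s = 900,
                                       boundary = "insulated"))
  expect_equal(res2$peak_dT, 2 * res$peak_dT, tolerance = 1e-9)
})

test_that("Gaussian source matches the Green's-function closed form", {
  gh <- gaussian_heat_cube(side_m = 0.040, spacing_m = 1e-3)
  tg <- thermal_grid(label = gh$label, spacing_m = 1e-3,
                     perfused_labels = integer(0))
  res <- solve_bioheat(gh$q, tg, bioheat_config(duration_s = 300))
  q0 <- 2 * 0.25 * 0.65e4
  ana <- gaussian_dT_centre(res$probe$t_s, q0, 2.1e-3, 0.528, 1040, 3600)
  sel <- res$probe$t_s > 50        # past the ramp-dominated first samples
  expect_lt(max(abs(res$probe$dT[sel] - ana[sel]) / ana[sel]), 0.03)
  # the infinite-time limit of the same Green's form is q0 sigma^2 / k
  expect_equal(gaussian_dT_centre(Inf, q0, 2.1e-3, 0.528, 1040, 3600),
               q0 * (2.1e-3)^2 / 0.528)
})

test_that("pulse-resolved and duty-averaged runs agree on slow scales", {
  n <- 7L
  tg <- thermal_grid(label = array(1L, c(n, n, n)), spacing_m = 1e-3)
  pt <- pulse_train(2e5, 0.1, 1, 60, ispta_w_cm2 = 0.5)
  isppa <- vox_volume(array(5, c(n, n, n)), 1e-3)
  qa <- heat_source(isppa, 0.25, pt, "duty-averaged")
  qp <- heat_source(isppa, 0.25, pt, "pulse-resolved")
  ra <- solve_bioheat(qa, tg, bioheat_config(duration_s = 60,
                                             boundary = "insulated"))
  rp <- solve_bioheat(qp, tg, bioheat_config(time_step_s = 5e-3,
                                             duration_s = 60,
                                             boundary = "insulated"))
  expect_lt(abs(rp$peak_dT - ra$peak_dT) / ra$peak_dT, 0.02)
})

test_that("stability violations are refused and degenerate series flagged", {
  tg <- thermal_grid(label = array(1L, c(5, 5, 5)), spacing_m = 0.5e-3)
  q <- vox_volume(array(100, c(5, 5, 5)), 0.5e-3)
  expect_error(solve_bioheat(q, tg, bioheat_config(time_step_s = 10)),
               "stability")
  expect_error(steady_state_time(
    structure(list(probe = tibble::tibble(t_s = 1:10, dT = rep(0, 10))),
              class = "thermal_result")), "no temperature elevation")
  # a step-to-constant series reaches steady state at its first sample
  res <- structure(list(probe = tibble::tibble(t_s = 1:10,
                                               dT = rep(0.5, 10))),
                   class = "thermal_result")
  expect_equal(steady_state_time(res), 1)
})

test_that("grid refinement leaves the Gaussian benchmark peak stable", {
  tg1 <- thermal_grid(label = gaussian_heat_cube(0.03, 1e-3)$label,
                      spacing_m = 1e-3)
  r1 <- solve_bioheat(gaussian_heat_cube(0.03, 1e-3)$q, tg1,
                      bioheat_config(duration_s = 400))
  gh2 <- gaussian_heat_cube(0.03, 0.5e-3)
  tg2 <- thermal_grid(label = gh2$label, spacing_m = 0.5e-3)
  r2 <- solve_bioheat(gh2$q, tg2, bioheat_config(duration_s = 400))
  expect_lt(abs(r1$peak_dT - r2$peak_dT) / r2$peak_dT, 0.02)
})
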