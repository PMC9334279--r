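test_that("duty cycle follows PD x PRF with the continuous-wave limit", {
  expect_equal(duty_cycle(pulse_train(2e5, 0.1, 1, 600, ispta_w_cm2 = 0.5)),
               0.10)
  expect_equal(duty_cycle(pulse_train(2e5, 0.1, 5, 600, ispta_w_cm2 = 0.5)),
               0.50)
  expect_equal(duty_cycle(pulse_train(2e5, 1, 1, 600, isppa_w_cm2 = 0.5)), 1)
  expect_error(pulse_train(2e5, 0.6, 2, 600, ispta_w_cm2 = 0.5), "overlap")
  expect_error(pulse_train(2e5, -0.1, 1, 600, ispta_w_cm2 = 0.5), "positive")
  expect_error(pulse_train(2e5, 0.1, 1, 600), "exactly one")
  expect_error(pulse_train(2e5, 0.1, 1, 600, ispta_w_cm2 = 0.5, pr_pa = 1e5),
               "exactly one")
})

test_that("pulse-average / temporal-average conversion round-trips", {
  expect_equal(isppa_for_ispta(0.5, 0.10), 5)
  expect_equal(isppa_for_ispta(0.5, 0.75), 0.5 / 0.75)
  expect_equal(isppa_for_ispta(3.2, 1), 3.2)
  expect_error(isppa_for_ispta(0.5, 0), "duty cycle")
  expect_error(isppa_for_ispta(0.5, 1.2), "duty cycle")
  for (dc in c(0.01, 0.1, 0.33, 0.5, 0.999, 1)) {
    expect_equal(ispta_from_isppa(isppa_for_ispta(0.7, dc), dc), 0.7)
  }
})

test_that("constant-I_SPTA tables match the printed exposure series", {
  # fixed PD 100 ms, PRF swept: DC 10..100%
  t1 <- sonication_table(c(.10, .25, .50, .75, 1), ispta_w_cm2 = 0.5,
                         pd_s = NULL, prf_hz = c(1, 2.5, 5, 7.5, 10))
  expect_equal(round(t1$isppa_w_cm2, 2), c(5, 2, 1, 0.67, 0.5))
  # fixed PD 100 ms at PRF 1..5 Hz: DC 10..50%
  t2 <- sonication_table(seq(.1, .5, by = .1), ispta_w_cm2 = 0.5, pd_s = 0.1)
  expect_equal(t2$prf_hz, c(1, 2, 3, 4, 5))
  expect_equal(round(t2$isppa_w_cm2, 2), c(5, 2.5, 1.67, 1.25, 1))
  expect_error(sonication_table(0.1, pd_s = 0.1, prf_hz = 1), "exactly one")
})

test_that("plane-wave pressure-intensity conversion matches the bench values", {
  # 5 W/cm2 pulse-average in 24 C water -> ~386 kPa peak-rarefactional
  pr <- pressure_from_intensity(5, medium_constants(997, 1494))
  expect_lt(abs(pr - 386e3) / 386e3, 0.01)
  # peak-to-peak is twice peak-rarefactional in the linear regime
  expect_equal(pressure_from_intensity(5, convention = "peak-to-peak"), 2 * pr)
  # simulated in-situ pair: 6.5 W/cm2 <-> ~874 kPa peak-to-peak
  pp <- pressure_from_intensity(6.5, medium_constants(998, 1482),
                                convention = "peak-to-peak")
  expect_lt(abs(pp - 873.7e3) / 873.7e3, 0.02)
  # exact algebraic inverse
  for (i in c(0.01, 0.5, 5, 50)) {
    expect_equal(intensity_from_pressure(pressure_from_intensity(i), ), i)
    expect_equal(
      intensity_from_pressure(
        pressure_from_intensity(i, convention = "peak-to-peak"),
        convention = "peak-to-peak"), i)
  }
  expect_error(pressure_from_intensity(-1), "positive")
})

test_that("pulse envelope gates the carrier and averages to the duty cycle", {
  pt <- pulse_train(2e5, 0.1, 1, 10, ispta_w_cm2 = 0.5)
  expect_identical(pulse_envelope(pt, 0.05), 1L)
  expect_identical(pulse_envelope(pt, 0.5), 0L)
  # 1 kHz sampling over 10 s; the pulse edge can quantize by at most one
  # sample per period, i.e. 10 samples in total
  ts <- seq(0, 10 - 1e-3, by = 1e-3)
  expect_lte(abs(mean(pulse_envelope(pt, ts)) - 0.10), 10 / length(ts))
  expect_error(pulse_envelope(pt, 11), "duration")
})

test_that("wavelength is c over f", {
  expect_equal(wavelength(200e3, 1500), 7.5e-3)
  expect_equal(wavelength(1e6, 1500), 1.5e-3)
  expect_equal(wavelength(200e3, 2800), 14e-3)
  expect_error(wavelength(0, 1500), "positive")
})

test_that("YAML configuration blocks build the package objects", {
  cfg <- read_config(system.file("extdata", "example_config.yaml",
                                 package = "tfusim"))
  expect_s3_class(cfg$sonication, "pulse_train")
  expect_equal(duty_cycle(cfg$sonication), 0.10)
  expect_equal(cfg$sonication$amplitude$kind, "ispta_w_cm2")
  expect_s3_class(cfg$transducer, "transducer_geometry")
  expect_equal(cfg$transducer$aperture_diameter_m, 0.028)
  expect_s3_class(cfg$skull_mapping, "property_mapping")
  expect_equal(cfg$skull_mapping$c_bone_m_s, 2800)
})
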