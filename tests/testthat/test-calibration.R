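test_that("parallel-plate capacitance follows eps * A / d", {
  expect_equal(capacitance(1, 1, 1), 1)
  expect_equal(capacitance(2, 3, 1.5), 4)
  expect_equal(capacitance(2, 6, 1.5), 2 * capacitance(2, 3, 1.5))
  expect_equal(capacitance(4, 3, 1.5), 2 * capacitance(2, 3, 1.5))
  expect_gt(capacitance(2, 3, 1), capacitance(2, 3, 2))
  expect_error(capacitance(1, 1, 0), "thickness")
})

test_that("mixture permittivity is the volume-weighted mean", {
  expect_equal(mixture_permittivity(1, eps_composite = 7), 1)
  expect_equal(mixture_permittivity(0, eps_composite = 7), 7)
  expect_equal(mixture_permittivity(0.5, eps_composite = 5), 3)
  v <- seq(0, 1, by = 0.1)
  eps <- mixture_permittivity(v, eps_composite = 4)
  expect_true(all(eps >= 1 & eps <= 4))
  expect_error(mixture_permittivity(0.5, eps_composite = 5, vol_composite = 0.6),
               "sum to 1")
  expect_error(mixture_permittivity(1.2, eps_composite = 5, vol_composite = -0.2),
               "fractions")
})

test_that("forward calibration matches the two printed sensitivities", {
  curve <- calibration_curve()
  expect_equal(pressure_to_relcap(0, curve), 0)
  expect_equal(pressure_to_relcap(100, curve), 1.26)
  expect_equal(pressure_to_relcap(500, curve), 0.0126 * 200 + 0.0038 * 300)
  expect_equal(pressure_to_relcap(500, curve), 3.66)
  expect_error(pressure_to_relcap(-1, curve), "range")
  expect_error(pressure_to_relcap(501, curve), "range")
})

test_that("forward calibration is continuous, monotone, with segment slopes", {
  curve <- calibration_curve()
  p <- seq(0, 500, by = 0.5)
  rc <- pressure_to_relcap(p, curve)
  expect_true(all(diff(rc) > 0))
  # finite-difference slopes recover each sensitivity
  slopes <- diff(rc) / diff(p)
  expect_equal(unique(round(slopes[p[-1] <= 200], 10)), 0.0126)
  expect_equal(unique(round(slopes[p[-length(p)] >= 200], 10)), 0.0038)
  # continuity at the breakpoint
  expect_equal(pressure_to_relcap(200 - 1e-9, curve),
               pressure_to_relcap(200 + 1e-9, curve), tolerance = 1e-6)
})

test_that("inverse calibration round-trips above the detection limit", {
  curve <- calibration_curve()
  expect_equal(relcap_to_pressure(0, curve), 0)
  expect_equal(relcap_to_pressure(1.26, curve), 100)
  p <- seq(curve$detection_limit, 500, length.out = 2001)
  back <- relcap_to_pressure(pressure_to_relcap(p, curve), curve)
  expect_equal(back, p, tolerance = 1e-9)
  # below the detection limit readings are censored to zero
  expect_equal(relcap_to_pressure(pressure_to_relcap(0.2, curve), curve), 0)
  expect_error(relcap_to_pressure(3.7, curve), "above the calibrated range")
})

test_that("calibration curve invariants are enforced", {
  expect_error(calibration_curve(sensitivity_low = 0.001), "sensitivity_low")
  expect_error(calibration_curve(detection_limit = 300), "detection_limit")
  expect_error(calibration_curve(baseline_capacitance = 0), "positive")
})

test_that("series calibration maps a relcap recording to kPa channel-wise", {
  curve <- calibration_curve()
  p_true <- matrix(seq(1, 480, length.out = 80), ncol = 8)
  raw <- pressure_series(pressure_to_relcap(p_true, curve), unit = "relcap")
  cal <- calibrate_series(raw, curve)
  expect_equal(cal$unit, "kPa")
  expect_equal(unname(cal$values), unname(p_true), tolerance = 1e-9)
  expect_error(calibrate_series(cal, curve), "already calibrated")
})
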