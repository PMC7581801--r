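# Charge calculus and pulse sampling

test_that("charge_per_phase matches closed-form phase areas", {
  # areas frozen from a 1e6-point midpoint integration of each envelope
  expect_equal(charge_per_phase("RECT", 100, 65), 6500e-6)
  expect_equal(charge_per_phase("TRI", 100, 100), 5000e-6)
  expect_equal(charge_per_phase("SINE", 100, 100), 6366.1977e-6,
               tolerance = 1e-7)
  expect_equal(charge_per_phase("LIN_DEC", 80, 100), 4000e-6)
})

test_that("shape tags are validated and display spellings accepted", {
  expect_identical(pulse_shape("Lin.Dec"), "LIN_DEC")
  expect_identical(pulse_shape("sine"), "SINE")
  expect_error(pulse_shape("SQUARE"), "unknown pulse shape")
  expect_error(charge_per_phase("RECT", -1, 65), "amplitude")
  expect_error(charge_per_phase("RECT", 100, 0), "pulse_width")
})

test_that("equivalent_amplitude inverts charge_per_phase for all shapes", {
  set.seed(11)
  for (shape in PULSE_SHAPES) {
    for (k in 1:25) {
      q <- runif(1, 1e-4, 1e-1)
      pw <- runif(1, 10, 500)
      a <- equivalent_amplitude(shape, q, pw)
      expect_equal(charge_per_phase(shape, a, pw), q, tolerance = 1e-12)
    }
  }
  # charge-matched amplitude ratios against a rectangular reference
  A <- 100; pw <- 65
  q <- charge_per_phase("RECT", A, pw)
  expect_equal(equivalent_amplitude("RECT", q, pw), A)
  expect_equal(equivalent_amplitude("SINE", q, pw), pi / 2 * A)
  expect_equal(equivalent_amplitude("TRI", q, pw), 2 * A)
})

test_that("charge_rate counts both phases and is linear in I and f", {
  base <- pulse_train("RECT", 100, 65, 100, 130)
  expect_equal(charge_rate(base), 2 * 0.0065 * 130)
  dbl <- pulse_train("RECT", 200, 65, 100, 130)
  expect_equal(charge_rate(dbl) / charge_rate(base), 2)
  f15 <- pulse_train("SINE", 80, 65, 100, 15)
  f180 <- pulse_train("SINE", 80, 65, 100, 180)
  expect_equal(charge_rate(f180) / charge_rate(f15), 12)
})

test_that("charge multipliers truncate to one decimal", {
  expect_equal(charge_multiplier(50, 15), 3.3)
  expect_equal(charge_multiplier(100, 15), 6.6)
  expect_equal(charge_multiplier(130, 15), 8.6)
  expect_equal(charge_multiplier(350, 15), 23.3)
  expect_equal(charge_multiplier(15, 15), 1.0)
  expect_equal(charge_multiplier(100, 15, truncate_1dp = FALSE), 20 / 3)
  expect_error(charge_multiplier(0, 15), "> 0")
})

test_that("teed reproduces the printed formula and its scalings", {
  expect_equal(teed(100, 130, 65, electrode_spec(1000)), 8.45e-14)
  expect_equal(teed(200, 130, 65, 1000) / teed(100, 130, 65, 1000), 4)
  expect_equal(teed(100, 130, 65, 2000), teed(100, 130, 65, 1000) / 2)
  expect_error(electrode_spec(0), "positive")
})

test_that("sample_pulse builds a charge-balanced biphasic pulse", {
  spec <- pulse_train("RECT", 100, 65, 100, 130)
  wf <- sample_pulse(spec, dt_us = 1)
  expect_length(wf$current_ua, 230)
  expect_identical(wf$current_ua[1:65], rep(-100, 65))   # cathodic first
  expect_identical(wf$current_ua[66:165], rep(0, 100))
  expect_identical(wf$current_ua[166:230], rep(100, 65))
  an <- sample_pulse(pulse_train("RECT", 100, 65, 100, 130,
                                 polarity = "anodic_first"))
  expect_identical(an$current_ua[1], 100)

  set.seed(21)
  for (shape in PULSE_SHAPES) {
    spec <- pulse_train(shape, runif(1, 10, 300), runif(1, 50, 200), 100, 130)
    wf <- sample_pulse(spec, dt_us = spec$pulse_width_us / 200)
    ch <- sampled_charge(wf)
    expect_lte(abs(ch$net_uc), spec$amplitude_ua * wf$dt_us * 1e-6)
    expect_equal(ch$per_phase_uc,
                 charge_per_phase(shape, spec$amplitude_ua,
                                  spec$pulse_width_us),
                 tolerance = 1e-3)
  }
  expect_error(sample_pulse(spec, dt_us = spec$pulse_width_us / 2),
               "too coarse")
})

test_that("sampled charge converges to the closed form as dt shrinks", {
  spec <- pulse_train("SINE", 120, 100, 100, 130)
  q <- charge_per_phase("SINE", 120, 100)
  err <- vapply(c(10, 1, 0.1), function(dt) {
    abs(sampled_charge(sample_pulse(spec, dt))$per_phase_uc - q)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[2] / q, 1e-3)
})

test_that("shape ordering in charge at fixed amplitude and width", {
  q <- vapply(PULSE_SHAPES, charge_per_phase, numeric(1),
              amplitude_ua = 100, pulse_width_us = 80)
  expect_gt(q[["RECT"]], q[["SINE"]])
  expect_gt(q[["SINE"]], q[["TRI"]])
  expect_equal(q[["TRI"]], q[["LIN_DEC"]])
})

test_that("pulse_train validates the period constraint", {
  expect_error(pulse_train("RECT", 100, 3000, 100, 200), "period")
  expect_silent(pulse_train("RECT", 100, 65, 100, 350))
})
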