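# Synthetic cohort generator

test_that("sample_animal is deterministic and respects its invariants", {
  cfg <- cohort_config(seed = 123)
  a1 <- sample_animal(cfg, 3)
  a2 <- sample_animal(cfg, 3)
  expect_identical(a1, a2)
  expect_false(identical(a1, sample_animal(cfg, 4)))
  for (i in 1:20) {
    a <- sample_animal(cfg, i)
    expect_gt(a$r_at_2I0, a$r_at_I0)
    expect_gte(a$r_at_I0, 0)
    expect_identical(a$shape_efficacy[["RECT"]], 1)
    expect_true(all(a$shape_efficacy <= 1))
    k <- a$shape_efficacy[["SINE"]]
    expect_true(k > 0.5 && k < 0.95)
    expect_identical(k, a$shape_efficacy[["TRI"]])
    expect_gt(a$I0_true_ua, 0)
  }
})

test_that("frequency gain has the plateau / low-frequency structure", {
  a <- sample_animal(cohort_config(seed = 1), 1)
  expect_equal(freq_gain(a, 130), 1)
  expect_equal(freq_gain(a, 15), 0.0625)
  expect_equal(freq_gain(a, c(50, 100, 180)), c(1, 1, 1))
  expect_equal(freq_gain(a, 250), 1.75)
  # linear interpolation between knots, constant extrapolation outside
  expect_equal(freq_gain(a, 32.5), (0.0625 + 1) / 2)
  expect_equal(freq_gain(a, 1000), 1.75)
})

test_that("expected_rotations reproduces the dose-response anchors", {
  a <- fixed_animal(I0_ua = 60, r2 = 6)
  tr <- function(amp, shape = "RECT", f = 130, pw = 65) {
    pulse_train(shape, amp, pw, 100, f)
  }
  expect_equal(expected_rotations(a, tr(60)), 0.25)
  expect_equal(expected_rotations(a, tr(120)), 6)
  # charge-matched non-Rect at 2x charge == Rect at kappa*2 = 1.5x
  q0 <- charge_per_phase("RECT", 60, 100)
  sine2 <- tr(equivalent_amplitude("SINE", 2 * q0, 100), "SINE", pw = 100)
  rect15 <- tr(90, "RECT", pw = 100)
  expect_equal(expected_rotations(a, sine2), expected_rotations(a, rect15))
  # sub-threshold responses clip at zero
  expect_equal(expected_rotations(a, tr(10)), 0)
  # episode scaling is linear in duration
  expect_equal(expected_rotations(a, tr(120), episode_s = 15), 3)
})

test_that("simulate_session is reproducible and matches the noise-free closed form", {
  cfg <- noisefree_config(seed = 2)
  a <- fixed_animal(I0_ua = 60, r2 = 6, config = cfg)
  # single-episode protocol with R = 4 rotations expected
  amp <- 60 * (1 + (4 - 0.25) / 5.75)
  p <- build_amplitude_protocol(amp)
  w <- episode_windows(p)[1, ]
  traj <- simulate_session(a, p, cfg, seed = 9)
  f <- episode_features(traj, w$start_s, w$end_s + cfg$dt_s / 2)
  omega_bar <- 360 * 4 / 30
  expect_lt(abs(f$net_rotation * 360 - 1440), 2 * cfg$onset_tau_s * omega_bar)
  expect_gt(f$net_rotation * 360, 1440 * ramp_fraction(30, 1) - 5)

  cfg2 <- cohort_config(seed = 2)
  a2 <- sample_animal(cfg2, 1)
  t1 <- simulate_session(a2, p, cfg2, seed = 7)
  t2 <- simulate_session(a2, p, cfg2, seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_session(a2, p, cfg2, seed = 8)
  expect_false(identical(t1$angle_deg, t3$angle_deg))
  # angular rate stays physiologically bounded
  expect_lt(max(abs(diff(t1$angle_deg))) / cfg2$dt_s, 720)
  # position stays inside the bowl
  expect_true(all(t1$x_cm^2 + t1$y_cm^2 <= cfg2$bowl_radius_cm^2 + 1e-9))
  expect_error(simulate_session(a2, p, cohort_config(dt_s = 2), 1),
               "dt_s")
})

test_that("titration recovers the analytic threshold and applies exclusions", {
  cfg <- noisefree_config(seed = 3)
  a <- fixed_animal(I0_ua = 60, r2 = 6, config = cfg)
  tmpl <- pulse_train("RECT", 1, 65, 100, 130)
  step <- 0.5
  i0 <- titrate_I0(a, cfg, tmpl, grid_step_ua = step)
  # closed-form inversion of the dose-response at the 30-degree floor
  rf <- ramp_fraction(30, cfg$onset_tau_s)
  a_min <- 60 * (1 + (30 / 360 / rf - 0.25) / 5.75)
  expect_false(is_excluded(i0))
  expect_lt(abs(i0 - a_min), 2 * step)
  # the probe at the returned amplitude must sit inside [30, 180)
  R <- expected_rotations(a, pulse_train("RECT", i0, 65, 100, 130))
  expect_lt(R * 360 * rf, 180)
  expect_gte(R * 360, 30)

  expect_true(is_excluded(titrate_I0(fixed_animal(prone = TRUE), cfg, tmpl)))
  # hypersensitive animal: already past 180 degrees at the first grid point
  hyper <- fixed_animal(I0_ua = 1, r2 = 20, config = cfg)
  expect_true(is_excluded(titrate_I0(hyper, cfg, tmpl, grid_step_ua = 5)))
})

test_that("exclusion fraction tracks the configured probability", {
  draws <- vapply(1:600, function(i) {
    sample_animal(cohort_config(seed = 99), i)$dyskinesia_prone
  }, logical(1))
  phat <- mean(draws)
  se3 <- 3 * sqrt(1 / 3 * 2 / 3 / 600)
  expect_lt(abs(phat - 1 / 3), se3)
})

test_that("apomorphine challenge separates lesioned from control animals", {
  cfg <- noisefree_config(seed = 4, dt_s = 1)
  a <- fixed_animal(config = cfg)
  tr <- apomorphine_challenge(a, lesioned = TRUE, seed = 1, config = cfg,
                              rate_rpm = 5)
  expect_equal(tr$angle_deg[length(tr$angle_deg)] / 360, 150)
  expect_true(assess_lesion(tr))

  cfg2 <- cohort_config(seed = 4, dt_s = 1)
  pass <- vapply(1:100, function(s) {
    assess_lesion(apomorphine_challenge(a, TRUE, seed = s, config = cfg2))
  }, logical(1))
  fail <- vapply(1:100, function(s) {
    assess_lesion(apomorphine_challenge(a, FALSE, seed = s, config = cfg2))
  }, logical(1))
  expect_gte(mean(pass), 0.9)
  expect_lte(mean(fail), 0.02)
})
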