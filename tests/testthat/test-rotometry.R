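# Per-episode rotometry features

test_that("constant-rate window closed forms hold", {
  traj <- const_rate_traj(48, 30)
  f <- episode_features(traj, 0, 30.001)
  expect_equal(f$max_rotation, 4)
  expect_equal(f$net_rotation, 4)
  expect_equal(f$auc_rot_s, 60) # omega*T^2 / (2*360)
  expect_true(is.na(f$distance_cm))
})

test_that("overshoot-and-return windows split max and net rotation", {
  traj <- angular_trajectory(c(0, 10, 20), c(0, 400, 350))
  f <- episode_features(traj, 0, 20.5)
  expect_equal(f$max_rotation, 400 / 360)
  expect_equal(f$net_rotation, 350 / 360)
})

test_that("distance is a pure path length, decoupled from rotation", {
  # 10-cm square walked once with flat angle
  x <- c(0, 10, 10, 0, 0)
  y <- c(0, 0, 10, 10, 0)
  traj <- angular_trajectory(0:4, rep(0, 5), x, y)
  f <- episode_features(traj, 0, 4.5)
  expect_equal(f$distance_cm, 40)
  expect_equal(f$max_rotation, 0)
  # rigid rotation + translation of the frame leaves distance unchanged
  th <- 0.7
  xr <- 3 + x * cos(th) - y * sin(th)
  yr <- -2 + x * sin(th) + y * cos(th)
  fr <- episode_features(angular_trajectory(0:4, rep(0, 5), xr, yr), 0, 4.5)
  expect_equal(fr$distance_cm, f$distance_cm)
})

test_that("features are invariant to a constant angle offset", {
  set.seed(31)
  t <- seq(0, 40, by = 0.05)
  ang <- cumsum(rnorm(length(t), 2, 5))
  f1 <- episode_features(angular_trajectory(t, ang), 5, 35)
  f2 <- episode_features(angular_trajectory(t, ang + 987.6), 5, 35)
  expect_equal(f1, f2)
})

test_that("features agree with a brute-force oracle on random trajectories", {
  set.seed(32)
  for (k in 1:5) {
    t <- sort(runif(400, 0, 60))
    t <- t[c(TRUE, diff(t) > 1e-6)]
    ang <- cumsum(rnorm(length(t), 0, 20))
    x <- cumsum(rnorm(length(t), 0, 1))
    y <- cumsum(rnorm(length(t), 0, 1))
    traj <- angular_trajectory(t, ang, x, y)
    w0 <- 10; w1 <- 50
    f <- episode_features(traj, w0, w1)
    # independent straight-line reimplementation
    idx <- which(t >= w0 & t < w1)
    r <- (ang[idx] - ang[idx][1]) / 360
    mx <- -Inf; au <- 0; dd <- 0
    for (i in seq_along(idx)) {
      if (r[i] > mx) mx <- r[i]
      if (i > 1) {
        au <- au + (t[idx[i]] - t[idx[i - 1]]) * (r[i] + r[i - 1]) / 2
        dd <- dd + sqrt((x[idx[i]] - x[idx[i - 1]])^2 +
                          (y[idx[i]] - y[idx[i - 1]])^2)
      }
    }
    expect_equal(f$max_rotation, mx, tolerance = 1e-9)
    expect_equal(f$net_rotation, r[length(r)], tolerance = 1e-9)
    expect_equal(f$auc_rot_s, au, tolerance = 1e-9)
    expect_equal(f$distance_cm, dd, tolerance = 1e-9)
  }
})

test_that("degenerate windows are rejected", {
  traj <- const_rate_traj(10, 30)
  expect_error(episode_features(traj, 40, 50), "fewer than 2 samples")
})

test_that("session_features lays out one labelled row per ON episode", {
  cfg <- noisefree_config(seed = 6)
  a <- fixed_animal(I0_ua = 60, r2 = 6, config = cfg)
  p <- build_amplitude_protocol(60)
  traj <- simulate_session(a, p, cfg, seed = 1)
  f <- session_features(traj, p)
  expect_equal(nrow(f), 5)
  expect_equal(f$label, episode_windows(p)$label)
  expect_equal(f$charge_rate_ucs,
               vapply(seq_len(5), function(i) {
                 charge_rate(window_train(episode_windows(p)[i, ]))
               }, numeric(1)))
  # noise-free rows track the closed-form dose-response up to the ramp
  R_exp <- vapply(seq_len(5), function(i) {
    expected_rotations(a, window_train(episode_windows(p)[i, ]))
  }, numeric(1))
  ramp_loss <- (1 - ramp_fraction(30, cfg$onset_tau_s)) * R_exp + 0.05
  expect_true(all(abs(f$max_rotation - R_exp) <= ramp_loss + 1e-9))
  # a truncated trajectory names the uncovered episodes
  short <- angular_trajectory(traj$time_s[1:100], traj$angle_deg[1:100])
  expect_error(session_features(short, p), "2xI0")
})

test_that("lesion criterion sits exactly at 3 rotations per minute", {
  t <- seq(0, 1800, by = 1)
  expect_true(assess_lesion(angular_trajectory(t, 90 * 360 * t / 1800)))
  expect_false(assess_lesion(angular_trajectory(t, 89 * 360 * t / 1800)))
  # ipsiversive (clockwise, negative) rotation never qualifies
  expect_false(assess_lesion(angular_trajectory(t, -120 * 360 * t / 1800)))
  expect_error(assess_lesion(const_rate_traj(10, 60)), "shorter")
})
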