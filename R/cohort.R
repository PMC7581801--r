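# Synthetic hemi-parkinsonian cohort ----------------------------------------
#
# Phenomenological behavior model: each animal carries a latent current
# threshold I0, a linear dose-response in the charge multiplier, a
# frequency gain curve with a 50-180 Hz plateau, and per-shape efficacy
# factors kappa < 1 for non-rectangular envelopes. Rotation direction is
# signed contralateral-positive (anti-clockwise for the right-hemisphere
# lesion these experiments model).

#' Cohort configuration
#'
#' Population-level parameters of the synthetic cohort plus simulation
#' settings. Defaults encode the reference experiment: 9 lesioned rats of
#' which about one third are excluded as over-sensitive, thresholds around
#' 60 uA, a corner-free bowl arena, 10 Hz sampling and ~1 s onset kinetics
#' of the transient rotation.
#'
#' @param n_animals cohort size (>= 1).
#' @param seed root seed; every animal / session / challenge derives its
#'   own stream from it, so any unit is reproducible in isolation.
#' @param I0_log_mean,I0_log_sd lognormal threshold distribution (uA scale).
#' @param exclusion_prob probability of the dyskinesia-prone phenotype
#'   excluded at titration.
#' @param bowl_radius_cm arena radius.
#' @param dt_s simulation step, s (must be <= 1).
#' @param onset_tau_s first-order onset/offset time constant of the
#'   rotation rate, s.
#' @param sigma_rate_dps white angular-rate noise, deg/s, added each step.
#' @param sigma_off_dps additional rate noise during DBS-off periods,
#'   deg/s (off-period drift).
#' @param speed_gain_cm_per_deg locomotor speed gained per deg/s of
#'   rotation rate.
#' @param base_speed_cms baseline ambulation speed, cm/s.
#' @param detect_min_deg lower detection bound of the titration window,
#'   deg per 30 s (the upper bound is the 180 deg threshold criterion).
#' @param titrate_max_ua upper end of the titration amplitude grid, uA.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 9L, seed = 1L,
                          I0_log_mean = log(60), I0_log_sd = 0.3,
                          exclusion_prob = 1 / 3,
                          bowl_radius_cm = 20, dt_s = 0.1,
                          onset_tau_s = 1,
                          sigma_rate_dps = 10, sigma_off_dps = 2,
                          speed_gain_cm_per_deg = 0.15,
                          base_speed_cms = 1,
                          detect_min_deg = 30, titrate_max_ua = 500) {
  stopifnot(n_animals >= 1, dt_s > 0,
            exclusion_prob >= 0, exclusion_prob <= 1,
            bowl_radius_cm > 0, onset_tau_s > 0,
            sigma_rate_dps >= 0, sigma_off_dps >= 0)
  structure(
    list(n_animals = as.integer(n_animals), seed = as.integer(seed),
         I0_log_mean = I0_log_mean, I0_log_sd = I0_log_sd,
         exclusion_prob = exclusion_prob, bowl_radius_cm = bowl_radius_cm,
         dt_s = dt_s, onset_tau_s = onset_tau_s,
         sigma_rate_dps = sigma_rate_dps, sigma_off_dps = sigma_off_dps,
         speed_gain_cm_per_deg = speed_gain_cm_per_deg,
         base_speed_cms = base_speed_cms,
         detect_min_deg = detect_min_deg, titrate_max_ua = titrate_max_ua),
    class = "cohort_config")
}

# Deterministic child seed for (stream, index) under one root seed.
# Kept below 2^31 - 1; streams: 1 animal draw, 2 session, 3 challenge.
.child_seed <- function(seed, stream, index) {
  s <- (abs(as.double(seed)) * 48271 + stream * 1299721 +
          as.double(index) * 7919) %% 2147483647
  as.integer(s)
}

.rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower && x < upper) break
    }
    out[i] <- x
  }
  out
}

# Frequency gain knots shared across animals: flat therapeutic plateau
# 50-180 Hz (gain 1), strong attenuation at 15 Hz (0.25/4 = 0.0625) and a
# saturating step up at 250-350 Hz.
.FREQ_KNOTS <- list(hz = c(15, 50, 100, 130, 180, 250, 350),
                    gain = c(0.0625, 1, 1, 1, 1, 1.75, 1.75))

#' Draw one synthetic hemi-parkinsonian animal
#'
#' Deterministic given `(config$seed, index)`. Latent parameters:
#' threshold `I0_true_ua ~ lognormal`, dose-response anchors
#' `r_at_I0 = 0.25` and `r_at_2I0 ~ N(6, 1)` rotations per 30 s
#' (truncated > 1), shared shape-efficacy factor
#' `kappa ~ N(0.75, 0.05)` truncated to (0.5, 0.95) for the Sine / Tri /
#' Lin.Dec envelopes with `kappa(Rect) = 1`, and a Bernoulli
#' dyskinesia-prone flag with probability `config$exclusion_prob`.
#'
#' @param config a [cohort_config()].
#' @param index 1-based animal index.
#' @return An object of class `animal_model`.
#' @export
sample_animal <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"), index >= 1)
  set.seed(.child_seed(config$seed, 1L, index))
  I0 <- stats::rlnorm(1, config$I0_log_mean, config$I0_log_sd)
  r2 <- .rnorm_trunc(1, 6, 1, lower = 1)
  kap <- .rnorm_trunc(1, 0.75, 0.05, lower = 0.5, upper = 0.95)
  prone <- stats::runif(1) < config$exclusion_prob
  structure(
    list(id = sprintf("rat%02d", index), index = as.integer(index),
         I0_true_ua = I0, r_at_I0 = 0.25, r_at_2I0 = r2,
         freq_knots = .FREQ_KNOTS,
         shape_efficacy = c(RECT = 1, SINE = kap, TRI = kap, LIN_DEC = kap),
         dyskinesia_prone = prone,
         sigma_rate_dps = config$sigma_rate_dps,
         sigma_off_dps = config$sigma_off_dps,
         speed_gain_cm_per_deg = config$speed_gain_cm_per_deg,
         base_speed_cms = config$base_speed_cms),
    class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  cat(sprintf(
    "<animal_model> %s: I0 = %.1f uA, r(2xI0) = %.2f rot/30 s, kappa = %.2f%s\n",
    x$id, x$I0_true_ua, x$r_at_2I0, x$shape_efficacy[["SINE"]],
    if (x$dyskinesia_prone) " [dyskinesia-prone]" else ""))
  invisible(x)
}

#' Frequency response gain of an animal
#'
#' Linear interpolation between the gain knots, normalized so the gain at
#' 130 Hz equals 1; constant extrapolation beyond the outermost knots.
#'
#' @param animal an `animal_model`.
#' @param frequency_hz frequency (vectorized), Hz.
#' @return Dimensionless gain.
#' @export
freq_gain <- function(animal, frequency_hz) {
  stats::approx(animal$freq_knots$hz, animal$freq_knots$gain,
                xout = frequency_hz, rule = 2)$y
}

#' Expected rotations of an animal under one pulse train
#'
#' Linear dose-response in the effective charge multiplier
#' `m_eff = kappa(shape) * Q(train) / Q(threshold)`, where `Q(threshold)`
#' is the charge per phase of a rectangular pulse at the animal's latent
#' threshold and the train's own pulse width:
#' `R = max(0, r_at_I0 + (r_at_2I0 - r_at_I0) * (m_eff - 1)) * g(f)`,
#' with `g` the frequency gain (`g(130 Hz) = 1`). `R` is scaled linearly
#' from the 30-s anchor to `episode_s` (the underlying rotation *rate* is
#' duration-independent).
#'
#' @param animal an `animal_model`.
#' @param train a [pulse_train()].
#' @param episode_s episode duration, s.
#' @return Expected rotation count over the episode (noise-free,
#'   ramp-free).
#' @export
expected_rotations <- function(animal, train, episode_s = 30) {
  stopifnot(inherits(animal, "animal_model"), inherits(train, "pulse_train"))
  m <- charge_per_phase(train$shape, train$amplitude_ua,
                        train$pulse_width_us) /
    charge_per_phase("RECT", animal$I0_true_ua, train$pulse_width_us)
  m_eff <- animal$shape_efficacy[[train$shape]] * m
  base <- animal$r_at_I0 + (animal$r_at_2I0 - animal$r_at_I0) * (m_eff - 1)
  max(0, base) * freq_gain(animal, train$frequency_hz) * episode_s / 30
}

#' Simulate one session's angular / positional trajectory
#'
#' Discrete-time simulation at `config$dt_s`: the target angular rate is
#' `360 * R / duration` deg/s during each DBS-on episode (R from
#' [expected_rotations()]) and 0 during off periods; the realized mean
#' rate follows the target through a first-order filter with time
#' constant `config$onset_tau_s` (the transient onset/offset ramp).
#' White rate noise of sd `sigma_rate_dps` is added every step and an
#' extra `sigma_off_dps` during off periods. Locomotion: the heading
#' equals the cumulative angle (plus a random initial heading), speed is
#' `base_speed + speed_gain * |rate|`, and positions are folded back
#' radially at the bowl wall. Bit-identical for identical `(seed)`.
#'
#' @param animal an `animal_model`.
#' @param protocol a `session_protocol`.
#' @param config a [cohort_config()].
#' @param seed session seed.
#' @param position simulate the (x, y) track as well (default TRUE); with
#'   FALSE the trajectory carries angles only, which is considerably
#'   faster for angle-only analyses.
#' @return An [angular_trajectory()].
#' @export
simulate_session <- function(animal, protocol, config, seed,
                             position = TRUE) {
  stopifnot(inherits(animal, "animal_model"),
            inherits(protocol, "session_protocol"),
            inherits(config, "cohort_config"))
  dt <- config$dt_s
  if (dt > 1) stop("config$dt_s must be <= 1 s for adequate resolution",
                   call. = FALSE)
  wins <- episode_windows(protocol)
  total_s <- max(protocol$episodes$start_s + protocol$episodes$duration_s)
  n <- as.integer(ceiling(total_s / dt - 1e-9))
  t_left <- (seq_len(n) - 1) * dt # step k covers [t_left, t_left + dt)
  target <- numeric(n)
  on_mask <- logical(n)
  for (i in seq_len(nrow(wins))) {
    idx <- t_left >= wins$start_s[i] - 1e-9 & t_left < wins$end_s[i] - 1e-9
    R <- expected_rotations(animal, window_train(wins[i, ]),
                            episode_s = wins$end_s[i] - wins$start_s[i])
    target[idx] <- 360 * R / (wins$end_s[i] - wins$start_s[i])
    on_mask[idx] <- TRUE
  }
  # exact discretization of d(omega)/dt = (target - omega) / tau
  a <- exp(-dt / config$onset_tau_s)
  omega <- as.numeric(stats::filter((1 - a) * target, a,
                                    method = "recursive"))
  set.seed(.child_seed(seed, 2L, animal$index))
  heading0 <- stats::runif(1, 0, 360)
  rate <- omega + stats::rnorm(n, 0, animal$sigma_rate_dps)
  if (any(!on_mask)) {
    drift <- stats::rnorm(n, 0, animal$sigma_off_dps)
    rate[!on_mask] <- rate[!on_mask] + drift[!on_mask]
  }
  angle <- c(0, cumsum(rate * dt))
  time_s <- (0:n) * dt
  x <- y <- NULL
  if (position) {
    speed <- animal$base_speed_cms +
      animal$speed_gain_cm_per_deg * abs(rate)
    theta <- (angle[-1] + heading0) * pi / 180
    sx <- speed * dt * cos(theta)
    sy <- speed * dt * sin(theta)
    x <- y <- numeric(n + 1)
    px <- py <- 0
    rad <- config$bowl_radius_cm
    for (k in seq_len(n)) {
      nx <- px + sx[k]
      ny <- py + sy[k]
      rr <- sqrt(nx^2 + ny^2)
      if (rr > rad) { # radial fold-back at the wall
        f <- max(0, 2 * rad - rr) / rr
        nx <- nx * f
        ny <- ny * f
      }
      x[k + 1] <- px <- nx
      y[k + 1] <- py <- ny
    }
  }
  angular_trajectory(time_s, angle, x, y,
                     meta = list(animal = animal$id, seed = seed,
                                 paradigm = protocol$paradigm,
                                 I0_ua = animal$I0_true_ua))
}

#' Titrate the individual threshold amplitude I0
#'
#' Noise-free 30-s probe episodes are simulated on an ascending amplitude
#' grid; the returned `I0` is the smallest amplitude whose maximum
#' cumulative rotation lies in the detection window
#' `[detect_min_deg, 180)` degrees. Dyskinesia-prone animals — and
#' animals already beyond 180 degrees at the first grid point — are
#' excluded (`NA` with attribute `excluded`), mirroring the removal of
#' over-sensitive animals before the reference experiments.
#'
#' @param animal an `animal_model`.
#' @param config a [cohort_config()].
#' @param train_template a [pulse_train()] giving shape, pulse width,
#'   interphase gap and frequency of the probes (its amplitude is
#'   ignored).
#' @param grid_step_ua titration grid step, uA. The default 5 uA matches
#'   manual titration practice; with steep dose-responses a finer grid
#'   may be needed for the detection window not to fall between grid
#'   points (a titration-failure error otherwise).
#' @return The titrated amplitude in uA, or `NA` carrying
#'   `attr(, "excluded") = TRUE`.
#' @seealso [is_excluded()]
#' @export
titrate_I0 <- function(animal, config, train_template, grid_step_ua = 5) {
  stopifnot(inherits(animal, "animal_model"),
            inherits(config, "cohort_config"),
            inherits(train_template, "pulse_train"), grid_step_ua > 0)
  if (animal$dyskinesia_prone) {
    return(structure(NA_real_, excluded = TRUE))
  }
  probe_max_deg <- function(amp) {
    tr <- pulse_train(train_template$shape, amp,
                      train_template$pulse_width_us,
                      train_template$interphase_us,
                      train_template$frequency_hz,
                      train_template$polarity)
    ep <- data.frame(label = "probe", start_s = 0, duration_s = 30,
                     on = TRUE, shape = tr$shape,
                     amplitude_ua = tr$amplitude_ua,
                     pulse_width_us = tr$pulse_width_us,
                     interphase_us = tr$interphase_us,
                     frequency_hz = tr$frequency_hz)
    prot <- .new_session_protocol(ep, "titration")
    cfg <- config
    cfg$sigma_rate_dps <- 0
    cfg$sigma_off_dps <- 0
    traj <- simulate_session(.quiet_animal(animal), prot, cfg, seed = 0L,
                             position = FALSE)
    max(traj$angle_deg)
  }
  grid <- seq(grid_step_ua, config$titrate_max_ua, by = grid_step_ua)
  first <- TRUE
  for (amp in grid) {
    m <- probe_max_deg(amp)
    if (first && m >= 180) {
      return(structure(NA_real_, excluded = TRUE))
    }
    first <- FALSE
    if (m >= config$detect_min_deg && m < 180) {
      return(amp)
    }
    if (m >= 180) {
      stop("titration failed: detection window [", config$detect_min_deg,
           ", 180) deg skipped between grid points; use a smaller ",
           "grid_step_ua", call. = FALSE)
    }
  }
  stop("titration failed: amplitude grid exhausted without detection",
       call. = FALSE)
}

# copy of an animal with noise silenced (for deterministic probes)
.quiet_animal <- function(animal) {
  animal$sigma_rate_dps <- 0
  animal$sigma_off_dps <- 0
  animal
}

#' Is a titration result an exclusion?
#' @param x return value of [titrate_I0()].
#' @return TRUE when the animal was excluded.
#' @export
is_excluded <- function(x) isTRUE(attr(x, "excluded"))

#' Simulate an apomorphine challenge
#'
#' Well-lesioned animals rotate contralaterally (anti-clockwise) at about
#' 5 +/- 1 rotations per minute for the 30 minutes after the agonist
#' injection; non-lesioned controls drift at 0.5 +/- 0.3 per minute.
#' Against the >= 3 rotations/min lesion criterion the default lesioned
#' distribution passes in ~98% of draws and the control essentially never
#' does.
#'
#' @param animal an `animal_model`.
#' @param lesioned simulate a successful 6-OHDA lesion (default TRUE).
#' @param duration_min trace duration, minutes.
#' @param seed challenge seed.
#' @param config a [cohort_config()] (step size and rate noise).
#' @param rate_rpm optional fixed rotation rate (rotations/min) overriding
#'   the random draw, for deterministic checks.
#' @return An [angular_trajectory()] (angles only).
#' @export
apomorphine_challenge <- function(animal, lesioned = TRUE,
                                  duration_min = 30, seed = 1L,
                                  config = cohort_config(),
                                  rate_rpm = NULL) {
  stopifnot(inherits(animal, "animal_model"), duration_min > 0)
  set.seed(.child_seed(seed, 3L, animal$index))
  rpm <- if (!is.null(rate_rpm)) rate_rpm
  else if (lesioned) stats::rnorm(1, 5, 1)
  else stats::rnorm(1, 0.5, 0.3)
  dt <- config$dt_s
  n <- as.integer(round(duration_min * 60 / dt))
  rate <- rpm * 360 / 60 + stats::rnorm(n, 0, animal$sigma_rate_dps)
  angular_trajectory((0:n) * dt, c(0, cumsum(rate * dt)),
                     meta = list(animal = animal$id, seed = seed,
                                 challenge = "apomorphine",
                                 lesioned = lesioned))
}
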