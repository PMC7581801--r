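# Shared fixtures, all built in code.

# cohort config with behavioral noise silenced (deterministic limit)
noisefree_config <- function(...) {
  cohort_config(sigma_rate_dps = 0, sigma_off_dps = 0, ...)
}

# animal with controlled latent parameters, built on top of the sampler
fixed_animal <- function(I0_ua = 60, r2 = 6, kappa = 0.75, prone = FALSE,
                         config = noisefree_config(), index = 1L) {
  a <- sample_animal(config, index)
  a$I0_true_ua <- I0_ua
  a$r_at_2I0 <- r2
  a$shape_efficacy <- c(RECT = 1, SINE = kappa, TRI = kappa,
                        LIN_DEC = kappa)
  a$dyskinesia_prone <- prone
  a
}

# constant-angular-rate trajectory over [0, T]; window end just past T so
# the half-open window convention still includes the final sample
const_rate_traj <- function(rate_dps, T_s = 30, dt = 0.01, x = NULL,
                            y = NULL) {
  t <- seq(0, T_s, by = dt)
  angular_trajectory(t, rate_dps * t, x, y)
}

# fraction of the asymptotic angle reached with a first-order onset ramp
ramp_fraction <- function(T_s, tau) (T_s - tau * (1 - exp(-T_s / tau))) / T_s
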