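# Independent oracles used to cross-check the package implementation.
# These re-code the model equations from scratch on purpose: keep them
# textually independent of the package internals.

# Brute-force fixed-step Euler integration of the coupled Process L /
# Process P equations under zero-order-hold light. `times`/`values` give
# the light samples (drive units); integration runs over [t0, t_end]
# segment by segment so the light discontinuities are honored exactly.
# Returns a data frame with the state at every segment boundary.
euler_pacemaker <- function(state0, times, values, cfg, t0, t_end,
                            dt = 0.5 / 3600) {
  x <- state0[["x"]]; xc <- state0[["xc"]]; n <- state0[["n"]]
  omega2 <- (24 / (cfg$period_correction * cfg$tau_x))^2
  c12 <- pi / 12
  bounds <- c(t0, times[times > t0 & times < t_end], t_end)
  Iseg <- values[pmax(findInterval(bounds[-length(bounds)], times), 1L)]
  nb <- length(Iseg)
  out_t <- numeric(nb + 1); out_x <- numeric(nb + 1)
  out_xc <- numeric(nb + 1); out_n <- numeric(nb + 1)
  out_t[1] <- t0; out_x[1] <- x; out_xc[1] <- xc; out_n[1] <- n
  for (s in seq_len(nb)) {
    len <- bounds[s + 1] - bounds[s]
    m <- max(1L, round(len / dt))
    h <- len / m
    a <- cfg$alpha0 * (Iseg[s] / cfg$I0)^cfg$p
    for (i in seq_len(m)) {
      pool <- if (cfg$process_l) 1 - n else 1
      B <- cfg$G * a * pool
      if (cfg$modulator)
        B <- B * (1 - cfg$modulator_coeff * x) * (1 - cfg$modulator_coeff * xc)
      dx <- c12 * (xc + B +
                     cfg$mu * (x / 3 + 4 * x^3 / 3 - 256 * x^7 / 105))
      dxc <- c12 * (cfg$q * B * xc - x * (omega2 + cfg$k * B))
      dn <- 60 * (a * (1 - n) - cfg$beta * n)
      x <- x + h * dx; xc <- xc + h * dxc; n <- n + h * dn
      if (n < 0) n <- 0 else if (n > 1) n <- 1
    }
    out_t[s + 1] <- bounds[s + 1]
    out_x[s + 1] <- x; out_xc[s + 1] <- xc; out_n[s + 1] <- n
  }
  data.frame(time = out_t, x = out_x, xc = out_xc, n = out_n)
}

# A regular 16:8 light/dark series (lights on wake..sleep) at the given
# level, used by several tests.
regular_schedule_series <- function(level, n_days, wake = 7, sleep = 23,
                                    dt_h = 0.05, unit = "cs") {
  tt <- seq(0, n_days * 24 - dt_h, by = dt_h)
  v <- ifelse(tt %% 24 >= wake & tt %% 24 < sleep, level, 0)
  light_series(tt, v, unit = unit)
}

# The study-conditions synthetic cohort shared by the evaluation tests:
# n = 20 subjects, generating chronotype 05:00 (no spread), 0.25-h
# observation noise, advance protocol, fixed seed.
make_reference_cohort <- function(preset = "advance", obs_noise_sd = 0.25,
                                  n = 20, seed = 42) {
  pre <- protocol_preset(preset, seed = seed)
  spec <- cohort_spec(n_subjects = n, true_init_cbt_min = 5,
                      chronotype_sd = 0, obs_noise_sd = obs_noise_sd,
                      baseline_schedule = pre$baseline,
                      intervention_schedule = pre$intervention, seed = seed)
  generate_cohort(spec, model_config())
}
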