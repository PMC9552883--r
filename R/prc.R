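# Phase response curve simulation: a standardized daily light pulse is
# delivered at a grid of circadian phases and the resulting steady phase
# shift is measured against an unstimulated control run.

#' Specification of a standardized light pulse protocol
#'
#' Mirrors the classic laboratory PRC protocols: a pulse of fixed level
#' and duration delivered on `n_cycles` consecutive days (default 3,
#' as in the three-pulse bright-light protocols), with an optional
#' constant background level between pulses.
#'
#' @param duration Pulse length, hours.
#' @param level Pulse light level, in the unit `unit`.
#' @param n_cycles Number of consecutive daily administrations.
#' @param background Light level between pulses (default 0 = darkness).
#' @param unit Unit the levels are expressed in (`"lux"`, `"cla"`,
#'   `"cs"`); converted to the model's drive unit when possible.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(duration = 6, level, n_cycles = 3, background = 0,
                       unit = c("cs", "cla", "lux")) {
  unit <- match.arg(unit)
  stopifnot(duration > 0, level >= 0, n_cycles >= 1, background >= 0)
  structure(list(duration = duration, level = level, n_cycles = n_cycles,
                 background = background, unit = unit),
            class = "pulse_spec")
}

# Build the stimulus series for one PRC arm: lead-in darkness, n_cycles
# daily pulses centred at the given absolute times, then dark washout.
.prc_series <- function(pulse, centers, t_end, sample_h = 0.1) {
  tt <- seq(0, t_end, by = sample_h)
  v <- rep(pulse$background, length(tt))
  for (ct in centers) {
    on <- tt >= ct - pulse$duration / 2 & tt < ct + pulse$duration / 2
    v[on] <- pulse$level
  }
  light_series(tt, v, unit = pulse$unit)
}

#' Compute a phase response curve
#'
#' For each phase on the grid the oscillator is initialized on the
#' dim-light limit cycle, run through a one-cycle dark lead-in, exposed
#' to `pulse$n_cycles` daily pulses whose midpoints land at the stated
#' circadian phase (hours relative to the initial CBT_min; 24-h spacing
#' between administrations), and then released into a dark washout of
#' `washout_cycles` cycles. The shift is the wrapped difference between
#' the final post-washout CBT_min of the stimulated run and of an
#' unstimulated control run sharing every setting except the pulse;
#' subtracting the control removes free-run drift exactly. Positive
#' shifts are delays.
#'
#' @param pulse A [pulse_spec()].
#' @param phase_grid Pulse-midpoint phases in hours relative to CBT_min
#'   (default 24 phases at 1-h spacing, -12 ... +11). Phases are
#'   circadian times and are reduced to (-12, 12]: a grid shifted by 24 h
#'   reproduces the curve exactly.
#' @param cfg A [model_config()]; the pulse levels are converted from
#'   `pulse$unit` to `cfg$input_unit` via the usual unit rules.
#' @param washout_cycles Dark cycles after the last pulse (at least 2).
#' @param options [solver_options()].
#' @return A `prc_curve`: data frame with columns `phase_h` and
#'   `shift_h`, with the pulse spec in an attribute.
#' @export
compute_prc <- function(pulse, phase_grid = seq(-12, 11), cfg = model_config(),
                        washout_cycles = 3, options = solver_options()) {
  stopifnot(inherits(pulse, "pulse_spec"))
  if (washout_cycles < 2)
    stop("washout_cycles must be at least 2 for a settled phase estimate")

  period <- free_run_period(cfg)
  phase_w <- wrap_signed(phase_grid, 24)
  lead_in <- period  # first post-lead-in CBT_min lands exactly at t = period
  t_last_center <- lead_in + (pulse$n_cycles - 1) * 24 + 12
  t_end <- t_last_center + pulse$duration / 2 + washout_cycles * cfg$tau_x

  run_arm <- function(level_series) {
    drv <- prepare_drive_series(level_series, cfg$input_unit, cfg$cs_params)
    # state at the limit-cycle minimum: free-run minima then fall at k * period
    s0 <- initialize_from_cbt_min(0, cfg, initial_light = 0, t0 = 0)
    traj <- integrate_pacemaker(s0, drv, cfg, options = options)
    mk <- find_cbt_min(traj, cfg)
    mk$abs_time_h[nrow(mk)]
  }

  ctrl_series <- .prc_series(pulse_spec(pulse$duration, 0, pulse$n_cycles,
                                        pulse$background, pulse$unit),
                             centers = numeric(0), t_end = t_end)
  t_ctrl <- run_arm(ctrl_series)

  shifts <- vapply(phase_w, function(ph) {
    centers <- lead_in + ph + 24 * (seq_len(pulse$n_cycles) - 1)
    ser <- .prc_series(pulse, centers, t_end)
    t_tr <- run_arm(ser)
    wrap_signed(t_tr - t_ctrl, period)
  }, numeric(1))

  out <- data.frame(phase_h = phase_grid, shift_h = shifts)
  attr(out, "pulse") <- pulse
  attr(out, "config") <- cfg
  class(out) <- c("prc_curve", "data.frame")
  out
}

#' Summarize a phase response curve
#'
#' @param curve A `prc_curve` from [compute_prc()].
#' @return List with `max_advance` (most negative shift, hours),
#'   `max_delay` (largest positive shift), `amplitude` (peak-to-trough,
#'   `max - min`), and `zero_crossing_phase` (phase of the first
#'   delay-to-advance sign change, by linear interpolation; `NA` for an
#'   all-zero or single-signed curve).
#' @export
prc_summary <- function(curve) {
  stopifnot(inherits(curve, "prc_curve"))
  sh <- curve$shift_h; ph <- curve$phase_h
  amp <- max(sh) - min(sh)
  crossing <- NA_real_
  if (any(sh > 0) && any(sh < 0)) {
    s <- sign(sh)
    idx <- which(s[-1] != s[-length(s)] & s[-1] != 0)
    if (length(idx)) {
      i <- idx[1]
      crossing <- ph[i] - sh[i] * (ph[i + 1] - ph[i]) / (sh[i + 1] - sh[i])
    }
  }
  list(max_advance = min(sh), max_delay = max(sh),
       amplitude = amp, zero_crossing_phase = crossing)
}

#' @export
print.prc_curve <- function(x, ...) {
  s <- prc_summary(x)
  cat(sprintf(
    "<prc_curve> %d phases | max delay %+.2f h | max advance %+.2f h | amplitude %.2f h\n",
    nrow(x), s$max_delay, s$max_advance, s$amplitude))
  invisible(x)
}

#' Plot a phase response curve
#'
#' Shift (hours; delays positive) against pulse-midpoint phase relative
#' to CBT_min.
#'
#' @param x A `prc_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.prc_curve <- function(x, ...) {
  plot(x$phase_h, x$shift_h, type = "b", pch = 16,
       xlab = "pulse midpoint phase relative to CBT_min (h)",
       ylab = "phase shift (h; delay > 0)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Write a PRC curve to CSV (`phase_h,shift_h`)
#' @param curve A `prc_curve`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_prc_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("phase_h", "shift_h")], path,
                   row.names = FALSE)
  invisible(path)
}
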