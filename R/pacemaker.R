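# Process L, the sensitivity-modulated photic drive, the Process P van der
# Pol oscillator, and the trajectory integrator.

#' Pacemaker state
#'
#' The oscillator state at one time point: the van der Pol state variables
#' `x` and `xc` (the `x` minimum marks CBT_min) and the Process L used-pool
#' fraction `n` in `[0, 1]`.
#'
#' @param x,xc Oscillator state variables (dimensionless, magnitude below
#'   5 -- the limit cycle has amplitude about 1).
#' @param n Fraction of used photoreceptor elements, in `[0, 1]`.
#' @return An object of class `pacemaker_state` (named numeric vector).
#' @export
pacemaker_state <- function(x, xc, n = 0) {
  stopifnot(is.finite(x), is.finite(xc), is.finite(n))
  if (abs(x) >= 5 || abs(xc) >= 5)
    stop("pacemaker_state: |x| and |xc| must be below 5")
  if (n < 0 || n > 1) stop("pacemaker_state: n must lie in [0, 1]")
  structure(c(x = x, xc = xc, n = n), class = "pacemaker_state")
}

#' Process L light-activation rate
#'
#' \eqn{\alpha(I) = \alpha_0 (I/I_0)^p} per minute: the rate at which
#' ready photoreceptor elements are activated by light `I` (in the
#' configured drive unit). It is 0 in darkness, equals `alpha0` at
#' `I = I0`, and is monotone increasing in `I`.
#'
#' @param I Nonnegative light value(s) in drive units.
#' @param cfg A [model_config()] (supplies `alpha0`, `p`, `I0`).
#' @return Activation rate(s), per minute.
#' @export
alpha_of_I <- function(I, cfg = model_config()) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("alpha_of_I: light must be finite and nonnegative")
  cfg$alpha0 * (I / cfg$I0)^cfg$p
}

#' Process L pool dynamics
#'
#' \eqn{\dot n = 60[\alpha(I)(1 - n) - \beta n]} in hours^-1 (the factor
#' 60 converts the per-minute rates to the hour time base). The fixed
#' point under constant light is \eqn{n_\infty = \alpha/(\alpha+\beta)}.
#'
#' @param n Used-pool fraction in `[0, 1]`.
#' @param I Light in drive units.
#' @param cfg A [model_config()].
#' @return dn/dt in hours^-1.
#' @export
process_l_rhs <- function(n, I, cfg = model_config()) {
  if (any(n < 0) || any(n > 1))
    stop("process_l_rhs: n must lie in [0, 1]")
  a <- alpha_of_I(I, cfg)
  60 * (a * (1 - n) - cfg$beta * n)
}

#' Photic drive onto Process P
#'
#' The raw drive is \eqn{\hat B = G\,\alpha(I)(1 - n)}; with the
#' sensitivity modulator it becomes \eqn{B = \hat B (1 - 0.4x)(1 -
#' 0.4x_c)}, making the effectiveness of a light exposure depend on the
#' oscillator's current phase. Bypassing Process L holds the adaptation
#' term `(1 - n)` at 1, so light feeds through as `G alpha(I)` without
#' light-history dependence.
#'
#' @param state A [pacemaker_state()] (or named vector with `x`, `xc`, `n`).
#' @param I Light in drive units.
#' @param cfg A [model_config()]; its `process_l` and `modulator` toggles
#'   select the bypass and the modulator.
#' @return Drive `B` (dimensionless). Zero whenever `I = 0`.
#' @export
photic_drive <- function(state, I, cfg = model_config()) {
  a <- alpha_of_I(I, cfg)
  pool <- if (cfg$process_l) 1 - state[["n"]] else 1
  B <- cfg$G * a * pool
  if (cfg$modulator)
    B <- B * (1 - cfg$modulator_coeff * state[["x"]]) *
             (1 - cfg$modulator_coeff * state[["xc"]])
  unname(B)
}

#' Process P van der Pol dynamics
#'
#' Right-hand side of the oscillator equations (see [model_config()] for
#' the full forms). At `B = 0`, `x = 0` this reduces to `dx/dt =
#' (pi/12) xc`, `dxc/dt = 0`.
#'
#' @param state A [pacemaker_state()].
#' @param B Photic drive from [photic_drive()].
#' @param cfg A [model_config()].
#' @return Named numeric `c(dx, dxc)` in hours^-1.
#' @export
process_p_rhs <- function(state, B, cfg = model_config()) {
  x <- state[["x"]]; xc <- state[["xc"]]
  if (!is.finite(x) || !is.finite(xc) || !is.finite(B))
    stop("process_p_rhs: non-finite state or drive (integration failure)")
  pi12 <- pi / 12
  omsq <- (24 / (cfg$period_correction * cfg$tau_x))^2
  dx <- pi12 * (xc + B + cfg$mu * (x / 3 + 4 * x^3 / 3 - 256 * x^7 / 105))
  dxc <- pi12 * (cfg$q * B * xc - x * (omsq + cfg$k * B))
  c(dx = dx, dxc = dxc)
}

# ---------------------------------------------------------------------------
# Integrator. Light is treated as a zero-order hold between samples, and the
# classical RK4 substeps are aligned to the sample boundaries so that no step
# straddles a light discontinuity. Within a segment the light (hence alpha)
# is constant, which makes the ODE smooth and RK4 at <= 6-min substeps
# effectively exact for this slow system (verified against a 0.5-s Euler
# brute-force oracle in the tests).

# Build the ZOH segment decomposition of a drive series over [t0, t1].
# Returns list(bounds, I) with length(bounds) = length(I) + 1. Gaps longer
# than max_gap are filled with darkness (warning).
.zoh_segments <- function(times, values, t0, t1, max_gap) {
  stopifnot(t1 >= t0)
  if (times[1] > t0 + 1e-9)
    stop("drive series does not cover the start of the integration span")
  keep <- times > t0 & times < t1
  bounds <- c(t0, times[keep], t1)
  # light in each segment = value at the latest sample <= segment start
  idx <- findInterval(bounds[-length(bounds)], times)
  I <- values[pmax(idx, 1L)]
  seglen <- diff(bounds)
  long <- seglen > max_gap + 1e-9
  if (any(long)) {
    warning(sprintf(
      "%d series gap(s) longer than %.0f min filled with darkness",
      sum(long), max_gap * 60))
    I[long] <- 0
  }
  drop <- seglen < 1e-12
  list(bounds = bounds, I = I, drop = drop)
}

# Core fixed-step RK4 over ZOH segments. state0 = c(x, xc, n). Fast path:
# everything inlined and scalar.
.rk4_core <- function(state0, bounds, I, cfg, opts) {
  a0 <- cfg$alpha0; beta <- cfg$beta; G <- cfg$G; p <- cfg$p; I0 <- cfg$I0
  mu <- cfg$mu; q <- cfg$q; k <- cfg$k
  mc <- if (cfg$modulator) cfg$modulator_coeff else 0
  usemod <- cfg$modulator
  usepool <- cfg$process_l
  pi12 <- pi / 12
  omsq <- (24 / (cfg$period_correction * cfg$tau_x))^2
  dlim <- opts$divergence_limit
  hmax <- opts$max_step

  nseg <- length(I)
  seglen <- diff(bounds)
  nsub <- pmax(1L, as.integer(ceiling(seglen / hmax - 1e-9)))
  nsub[seglen < 1e-12] <- 0L
  npts <- 1L + sum(nsub)
  tout <- numeric(npts); xout <- numeric(npts)
  xcout <- numeric(npts); nout <- numeric(npts)

  x <- state0[[1]]; xc <- state0[[2]]; n <- state0[[3]]
  tout[1] <- bounds[1]; xout[1] <- x; xcout[1] <- xc; nout[1] <- n
  j <- 1L
  alphas <- a0 * (I / I0)^p

  for (s in seq_len(nseg)) {
    m <- nsub[s]
    if (m == 0L) next
    h <- seglen[s] / m
    al <- alphas[s]
    Bg <- G * al
    tcur <- bounds[s]
    # derivative evaluations, light (hence alpha) constant within the segment
    f <- function(x, xc, n) {
      pool <- if (usepool) 1 - n else 1
      B <- Bg * pool
      if (usemod) B <- B * (1 - mc * x) * (1 - mc * xc)
      c(pi12 * (xc + B + mu * (x / 3 + 4 * x^3 / 3 - 256 * x^7 / 105)),
        pi12 * (q * B * xc - x * (omsq + k * B)),
        60 * (al * (1 - n) - beta * n))
    }
    for (i in seq_len(m)) {
      k1 <- f(x, xc, n)
      k2 <- f(x + h / 2 * k1[1], xc + h / 2 * k1[2], n + h / 2 * k1[3])
      k3 <- f(x + h / 2 * k2[1], xc + h / 2 * k2[2], n + h / 2 * k2[3])
      k4 <- f(x + h * k3[1], xc + h * k3[2], n + h * k3[3])
      x <- x + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      xc <- xc + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      n <- n + h / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3])
      if (n < 0) n <- 0 else if (n > 1) n <- 1
      tcur <- tcur + h
      j <- j + 1L
      tout[j] <- tcur; xout[j] <- x; xcout[j] <- xc; nout[j] <- n
    }
    if (!is.finite(x) || !is.finite(xc) || abs(x) > dlim || abs(xc) > dlim)
      stop(sprintf(
        "integration failure: state diverged (|x| or |xc| > %g) at t = %.2f h",
        dlim, tcur))
  }
  data.frame(time = tout[seq_len(j)], x = xout[seq_len(j)],
             xc = xcout[seq_len(j)], n = nout[seq_len(j)])
}

#' Propagate the pacemaker through a light series
#'
#' Integrates the coupled Process L / Process P equations over a light
#' series expressed in the model's drive units. Light is held constant
#' between samples (zero-order hold) and the RK4 substeps are aligned to
#' the sample boundaries; the substep never exceeds
#' `min(max_step, sampling interval)`, so the trajectory is returned at
#' 6-minute resolution or finer. Series gaps longer than
#' `options$max_gap` hours are filled with darkness (with a warning).
#'
#' @param state0 Initial [pacemaker_state()] (see
#'   [initialize_from_cbt_min()] to start on the dim-light limit cycle at
#'   a chosen phase).
#' @param drive Either the list returned by [prepare_drive_series()] or a
#'   raw [light_series()], which is first converted to
#'   `cfg$input_unit`.
#' @param cfg A [model_config()].
#' @param t_span Length-2 numeric, hours; defaults to the series' time
#'   range. A zero-length span returns just the initial state.
#' @param options A [solver_options()].
#' @return A `pacemaker_trajectory`: data frame with columns `time`, `x`,
#'   `xc`, `n` and the configuration in attributes.
#' @export
integrate_pacemaker <- function(state0, drive, cfg = model_config(),
                                t_span = NULL, options = solver_options()) {
  if (inherits(drive, "light_series"))
    drive <- prepare_drive_series(drive, cfg$input_unit, cfg$cs_params)
  stopifnot(is.list(drive), !is.null(drive$series), !is.null(drive$I0))
  if (!isTRUE(all.equal(drive$I0, cfg$I0, tolerance = 1e-8)))
    stop(sprintf("drive I0 (%g) does not match configuration I0 (%g)",
                 drive$I0, cfg$I0))
  ser <- drive$series
  if (is.null(t_span)) t_span <- range(ser$time)
  stopifnot(length(t_span) == 2, t_span[2] >= t_span[1])
  s0 <- c(state0[["x"]], state0[["xc"]], state0[["n"]])

  if (t_span[2] - t_span[1] < 1e-12) {
    traj <- data.frame(time = t_span[1], x = s0[1], xc = s0[2], n = s0[3])
  } else {
    seg <- .zoh_segments(ser$time, ser$value, t_span[1], t_span[2],
                         options$max_gap)
    traj <- .rk4_core(s0, seg$bounds, seg$I, cfg, options)
  }
  attr(traj, "config") <- cfg
  attr(traj, "I0") <- drive$I0
  class(traj) <- c("pacemaker_trajectory", "data.frame")
  traj
}

# Integrate in constant light (darkness by default) without a series.
.integrate_constant <- function(state0, t0, t1, cfg, I = 0,
                                options = solver_options()) {
  s0 <- c(state0[["x"]], state0[["xc"]], state0[["n"]])
  if (t1 - t0 < 1e-12)
    return(structure(
      data.frame(time = t0, x = s0[1], xc = s0[2], n = s0[3]),
      class = c("pacemaker_trajectory", "data.frame"), config = cfg))
  traj <- .rk4_core(s0, c(t0, t1), I, cfg, options)
  attr(traj, "config") <- cfg
  class(traj) <- c("pacemaker_trajectory", "data.frame")
  traj
}

#' @export
print.pacemaker_trajectory <- function(x, ...) {
  cat(sprintf("<pacemaker_trajectory> %d points, %.2f-%.2f h\n",
              nrow(x), x$time[1], x$time[nrow(x)]))
  invisible(x)
}

# Final state of a trajectory as a pacemaker_state.
.final_state <- function(traj) {
  i <- nrow(traj)
  pacemaker_state(traj$x[i], traj$xc[i], min(max(traj$n[i], 0), 1))
}
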