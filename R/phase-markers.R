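# Circadian phase markers: CBT_min extraction from trajectories, the
# CBT_min -> DLMO offset, and limit-cycle-based initialization at a
# requested CBT_min clock time.

#' Locate CBT_min markers in a trajectory
#'
#' The model equates circadian phase with the minimum of the oscillator
#' variable `x`: each local minimum of `x(t)` (refined by quadratic
#' interpolation through the three samples around the discrete minimum,
#' plus the configured `xmin_to_cbtmin_lag`) is one CBT_min. A candidate
#' minimum must be the lowest point within a +/- 6 h window, which
#' rejects small drive-induced wiggles; successive markers are therefore
#' separated by one circadian cycle (18-30 h). The corresponding DLMO is
#' attached at the configured offset (default CBT_min - 7 h).
#'
#' @param traj A `pacemaker_trajectory` spanning at least one full cycle.
#' @param cfg The [model_config()] (supplies `dlmo_offset` and
#'   `xmin_to_cbtmin_lag`); defaults to the trajectory's own config.
#' @return A `marker_set`: data frame with columns `cycle`,
#'   `abs_time_h` (absolute hours of CBT_min), `cbt_min_clock`,
#'   `dlmo_clock` (both mod 24).
#' @export
find_cbt_min <- function(traj, cfg = attr(traj, "config")) {
  stopifnot(is.data.frame(traj), all(c("time", "x") %in% names(traj)))
  if (is.null(cfg)) cfg <- model_config()
  t <- traj$time; x <- traj$x
  m <- length(x)
  if (m < 3L || (t[m] - t[1]) < 18)
    stop("insufficient span: trajectory must cover at least one circadian cycle")
  int <- which(diff(sign(diff(x))) > 0) + 1L  # strict local minima
  if (!length(int))
    stop("insufficient span: no local minimum of x found (flat or monotone trajectory)")
  # keep only minima that are global within +/- 6 h
  keep <- vapply(int, function(i) {
    w <- which(t >= t[i] - 6 & t <= t[i] + 6)
    x[i] <= min(x[w]) + 1e-15
  }, logical(1))
  int <- int[keep]
  if (!length(int))
    stop("insufficient span: no cycle-scale minimum of x found")
  # quadratic refinement through (t[i-1], t[i], t[i+1])
  tmin <- vapply(int, function(i) {
    t3 <- t[(i - 1):(i + 1)]; x3 <- x[(i - 1):(i + 1)]
    d21 <- t3[2] - t3[1]; d32 <- t3[3] - t3[2]
    num <- d21^2 * (x3[2] - x3[3]) - d32^2 * (x3[2] - x3[1])
    den <- d21 * (x3[2] - x3[3]) + d32 * (x3[2] - x3[1])
    if (abs(den) < 1e-300) return(t3[2])
    t3[2] - 0.5 * num / den
  }, numeric(1))
  tmin <- tmin + cfg$xmin_to_cbtmin_lag
  out <- data.frame(cycle = seq_along(tmin),
                    abs_time_h = tmin,
                    cbt_min_clock = tmin %% 24,
                    dlmo_clock = (tmin - cfg$dlmo_offset) %% 24)
  class(out) <- c("marker_set", "data.frame")
  out
}

#' DLMO clock time from a CBT_min clock time
#'
#' DLMO precedes CBT_min by a fixed offset (default 7 h):
#' `DLMO = (CBT_min - offset) mod 24`.
#'
#' @param cbt_min CBT_min clock time(s), decimal hours.
#' @param cfg A [model_config()] supplying `dlmo_offset`.
#' @return DLMO clock time(s) in `[0, 24)`.
#' @examples
#' dlmo_from_cbt_min(4)  # 21
#' @export
dlmo_from_cbt_min <- function(cbt_min, cfg = model_config()) {
  (cbt_min - cfg$dlmo_offset) %% 24
}

#' Export markers to CSV
#' @param markers A `marker_set` from [find_cbt_min()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(markers, path) {
  df <- data.frame(cycle = markers$cycle,
                   cbt_min_clock = markers$cbt_min_clock,
                   dlmo_clock = markers$dlmo_clock,
                   abs_time_h = markers$abs_time_h)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Dim-light limit cycle, computed once per Process P parameter set and
# cached: 100-cycle dark burn-in (coarse), then five cycles recorded at
# 1-min resolution from which the final full cycle is tabulated by phase
# (hours until the next x-minimum).

.lc_cache <- new.env(parent = emptyenv())

.lc_key <- function(cfg) {
  paste(format(c(cfg$mu, cfg$q, cfg$k, cfg$tau_x, cfg$period_correction),
               digits = 15), collapse = "|")
}

.limit_cycle <- function(cfg) {
  key <- .lc_key(cfg)
  hit <- .lc_cache[[key]]
  if (!is.null(hit)) return(hit)
  opts_coarse <- solver_options(max_step = 0.1, max_gap = Inf)
  opts_fine <- solver_options(max_step = 1 / 60, max_gap = Inf)
  s <- pacemaker_state(1, 0, 0)
  burn <- 95 * cfg$tau_x
  traj <- .integrate_constant(s, 0, burn, cfg, I = 0, options = opts_coarse)
  s2 <- .final_state(traj)
  fine <- .integrate_constant(s2, burn, burn + 5 * cfg$tau_x, cfg, I = 0,
                              options = opts_fine)
  mkcfg <- cfg
  mkcfg$xmin_to_cbtmin_lag <- 0  # tabulate raw x-minima; the lag is applied on lookup
  mk <- find_cbt_min(fine, cfg = mkcfg)
  nmk <- nrow(mk)
  if (nmk < 2L) stop("limit-cycle computation failed: fewer than two minima")
  ta <- mk$abs_time_h[nmk - 1L]; tb <- mk$abs_time_h[nmk]
  period <- tb - ta
  seg <- fine[fine$time >= ta - 1e-9 & fine$time < tb - 1e-9, ]
  phi <- tb - seg$time                    # hours until next x-minimum
  o <- order(phi)
  lc <- list(period = period,
             phi = phi[o], x = seg$x[o], xc = seg$xc[o])
  .lc_cache[[key]] <- lc
  lc
}

# Interpolate the limit-cycle state at phase phi (hours until next minimum).
.lc_state_at <- function(lc, phi) {
  phi <- phi %% lc$period
  # wrap the table for interpolation across the seam
  pgrid <- c(lc$phi, lc$phi[1] + lc$period)
  xg <- c(lc$x, lc$x[1]); xcg <- c(lc$xc, lc$xc[1])
  x <- stats::approx(pgrid, xg, xout = phi, rule = 2)$y
  xc <- stats::approx(pgrid, xcg, xout = phi, rule = 2)$y
  c(x = x, xc = xc)
}

#' Free-running period of the dark limit cycle
#'
#' Measures the interval between successive `x`-minima on the cached
#' dim-light limit cycle for the given Process P parameters. With the
#' built-in period correction this equals `tau_x` to within a few
#' hundredths of an hour.
#'
#' @param cfg A [model_config()].
#' @return Period in hours.
#' @export
free_run_period <- function(cfg = model_config()) {
  .limit_cycle(cfg)$period
}

#' Initialize the oscillator at a requested CBT_min clock time
#'
#' Returns a state on the dim-light limit cycle positioned so that, if
#' integration starts at absolute time `t0` and continues in darkness,
#' the next `x`-minimum (plus the configured lag) falls at the requested
#' clock time. The limit cycle is computed once per Process P parameter
#' set (dark burn-in, final cycle tabulated at 1-min resolution) and
#' cached. The Process L pool starts at its fixed point
#' `alpha(initial_light) / (alpha + beta)` (0 in darkness).
#'
#' @param clock_time Requested CBT_min clock time in `[0, 24)` (decimal
#'   hours or `"HH:MM"`).
#' @param cfg A [model_config()].
#' @param initial_light Light level (drive units) assumed before the
#'   simulation starts, setting the initial pool fraction.
#' @param t0 Absolute start time of the upcoming integration, hours.
#' @return A [pacemaker_state()].
#' @export
initialize_from_cbt_min <- function(clock_time, cfg = model_config(),
                                    initial_light = 0, t0 = 0) {
  clock_time <- parse_clock(clock_time)
  stopifnot(clock_time >= 0, clock_time < 24)
  lc <- .limit_cycle(cfg)
  phi <- (clock_time - cfg$xmin_to_cbtmin_lag - t0) %% 24
  st <- .lc_state_at(lc, phi)
  a <- alpha_of_I(initial_light, cfg)
  n0 <- a / (a + cfg$beta)
  pacemaker_state(st[["x"]], st[["xc"]], n0)
}
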