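# Synthetic Daysimeter-like light series and cohorts: wake/sleep schedules
# with indoor daytime light, timed light interventions, 30-180 s storage
# intervals, and model-generated "observed" DLMO shifts with configurable
# noise. Everything is a pure function of its spec (seed included).

#' Daily light-exposure schedule specification
#'
#' Emulates a wearable light logger recording a subject on a fixed
#' wake/sleep schedule: a baseline light level while awake with
#' right-skewed sample-to-sample variability (log-normal multiplicative
#' noise, emulating the large short-term fluctuation real loggers record
#' as the wearer moves between rooms and windows), darkness while asleep,
#' and optional timed daily interventions (e.g. a morning blue-light
#' pulse) that overwrite the baseline level within their clock windows.
#' Overlapping intervention windows resolve to the maximum level (with a
#' warning).
#'
#' The default day level (median CS 0.15) is a plausible ordinary indoor
#' exposure chosen for realism; typical indoor CS levels were not
#' reported for the field studies this generator emulates. Flat
#' multi-hour blocks of much stronger light are not something field
#' recordings produce, and can drive the Process-L-bypassed model variant
#' into unbounded growth (see the vignette).
#'
#' @param wake_time,sleep_time Clock hours (decimal or `"HH:MM"`).
#' @param day_level Light level while awake, in `unit`.
#' @param night_level Light level while asleep (default 0).
#' @param interventions List of `list(start =, end =, level =)` daily
#'   pulses (clock hours; windows may wrap midnight).
#' @param sample_interval_s Storage interval in seconds, 30-180 unless
#'   `strict = FALSE`.
#' @param n_days Number of days.
#' @param jitter_sd Day-to-day SD of wake/sleep times, hours.
#' @param day_level_sigma SD of the per-sample log-normal multiplicative
#'   noise on `day_level`, log units (default 0.3; 0 disables).
#' @param unit Unit of all levels.
#' @param start_day Integer day offset of the first sample (so an
#'   intervention segment can continue a baseline segment in absolute
#'   time).
#' @param seed RNG seed making the generated series reproducible.
#' @param strict Enforce the 30-180 s sampling-interval range.
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(wake_time = 7, sleep_time = 23, day_level = 0.15,
                          night_level = 0, interventions = list(),
                          sample_interval_s = 180, n_days = 7,
                          jitter_sd = 0, day_level_sigma = 0.3,
                          unit = c("cs", "cla", "lux"), start_day = 0,
                          seed = 1, strict = TRUE) {
  unit <- match.arg(unit)
  if (strict && (sample_interval_s < 30 || sample_interval_s > 180))
    stop("sample_interval_s must lie in [30, 180] (use strict = FALSE to override)")
  stopifnot(day_level >= 0, night_level >= 0, n_days >= 1, jitter_sd >= 0,
            day_level_sigma >= 0)
  structure(list(wake_time = parse_clock(wake_time),
                 sleep_time = parse_clock(sleep_time),
                 day_level = day_level, night_level = night_level,
                 interventions = interventions,
                 sample_interval_s = sample_interval_s, n_days = n_days,
                 jitter_sd = jitter_sd, day_level_sigma = day_level_sigma,
                 unit = unit, start_day = start_day, seed = seed),
            class = "schedule_spec")
}

#' Generate a synthetic light series from a schedule
#'
#' Deterministic for a fixed spec (the seed is part of the spec).
#'
#' @param spec A [schedule_spec()].
#' @return A [light_series()] with `spec$n_days * 86400 /
#'   spec$sample_interval_s` samples.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "schedule_spec"))
  dt <- spec$sample_interval_s / 3600
  n_per_day <- round(86400 / spec$sample_interval_s)
  with_local_seed(spec$seed, {
    times <- numeric(0); values <- numeric(0)
    for (d in seq_len(spec$n_days)) {
      day0 <- (spec$start_day + d - 1) * 24
      tt <- day0 + (seq_len(n_per_day) - 1) * dt
      clock <- tt %% 24
      wake <- (spec$wake_time + stats::rnorm(1, 0, spec$jitter_sd)) %% 24
      sleep <- (spec$sleep_time + stats::rnorm(1, 0, spec$jitter_sd)) %% 24
      awake <- if (wake <= sleep) clock >= wake & clock < sleep
               else clock >= wake | clock < sleep
      lev <- rep(spec$day_level, length(tt))
      if (spec$day_level_sigma > 0)
        lev <- lev * stats::rlnorm(length(tt),
                                   meanlog = -spec$day_level_sigma^2 / 2,
                                   sdlog = spec$day_level_sigma)
      v <- ifelse(awake, lev, spec$night_level)
      if (length(spec$interventions)) {
        iv <- rep(NA_real_, length(tt))
        for (intr in spec$interventions) {
          ws <- parse_clock(intr$start); we <- parse_clock(intr$end)
          inw <- if (ws <= we) clock >= ws & clock < we
                 else clock >= ws | clock < we
          overlap <- inw & !is.na(iv)
          if (any(overlap))
            warning("overlapping intervention windows; resolved by maximum level")
          iv[inw] <- pmax(iv[inw], intr$level, na.rm = TRUE)
        }
        v[!is.na(iv)] <- iv[!is.na(iv)]
      }
      times <- c(times, tt); values <- c(values, v)
    }
    # the CS metric saturates at its asymptote; clip noise excursions
    if (spec$unit == "cs") values <- pmin(values, 0.7)
    light_series(times, values, unit = spec$unit)
  })
}

#' Intervention-protocol presets
#'
#' Ready-made schedule pairs patterned on the field protocols the model
#' was evaluated against:
#' \describe{
#'   \item{`"advance"`}{2 h of blue light (CS 0.5) each morning after
#'     waking plus 3 h of orange-filtered (circadian-dark) light each
#'     evening, on a 90-min advanced sleep schedule.}
#'   \item{`"delay"`}{3 h of blue light (CS 0.5) each evening plus 2 h of
#'     orange-filtered light each morning.}
#'   \item{`"morning-blue"`}{1 h of blue light (CS 0.4) immediately after
#'     waking on an advanced sleep schedule.}
#'   \item{`"goggles"`}{Blue-light goggles (CS 0.5) for 2 h each morning,
#'     with orange-filtered glasses from 17:00 to bedtime.}
#' }
#' The baseline arm is the same schedule without interventions.
#'
#' @param name Preset name.
#' @param n_days_baseline,n_days_intervention Segment lengths in days
#'   (defaults: 5-day baseline, 7-day intervention).
#' @param sample_interval_s Storage interval, seconds.
#' @param seed RNG seed.
#' @return List with `baseline` and `intervention` [schedule_spec()]s;
#'   the intervention segment starts where the baseline ends.
#' @export
protocol_preset <- function(name = c("advance", "delay", "morning-blue",
                                     "goggles"),
                            n_days_baseline = 5, n_days_intervention = 7,
                            sample_interval_s = 180, seed = 1) {
  name <- match.arg(name)
  base_wake <- 7; base_sleep <- 23
  adv_wake <- 5.5; adv_sleep <- 21.5   # 90-min advanced schedule
  mk <- function(wake, sleep, interventions, n_days, start_day, seed_off)
    schedule_spec(wake_time = wake, sleep_time = sleep,
                  interventions = interventions,
                  sample_interval_s = sample_interval_s, n_days = n_days,
                  start_day = start_day, seed = seed + seed_off)
  int <- switch(name,
    "advance" = list(wake = adv_wake, sleep = adv_sleep, iv = list(
      list(start = adv_wake, end = adv_wake + 2, level = 0.5),
      list(start = adv_sleep - 3, end = adv_sleep, level = 0))),
    "delay" = list(wake = base_wake, sleep = base_sleep, iv = list(
      list(start = base_sleep - 3, end = base_sleep, level = 0.5),
      list(start = base_wake, end = base_wake + 2, level = 0))),
    "morning-blue" = list(wake = adv_wake, sleep = adv_sleep, iv = list(
      list(start = adv_wake, end = adv_wake + 1, level = 0.4))),
    "goggles" = list(wake = base_wake, sleep = base_sleep, iv = list(
      list(start = base_wake, end = base_wake + 2, level = 0.5),
      list(start = 17, end = base_sleep, level = 0))))
  list(baseline = mk(base_wake, base_sleep, list(), n_days_baseline, 0, 0),
       intervention = mk(int$wake, int$sleep, int$iv, n_days_intervention,
                         n_days_baseline, 1))
}

#' Synthetic cohort specification
#'
#' @param n_subjects Number of subjects.
#' @param true_init_cbt_min Cohort-center CBT_min clock time at baseline
#'   start (the generating chronotype).
#' @param chronotype_sd SD of per-subject chronotype around the center,
#'   hours.
#' @param obs_noise_sd SD of Gaussian observation noise added to the
#'   model-truth DLMO shift, hours (applied to the post-intervention
#'   night, so the shift noise SD equals `obs_noise_sd` exactly).
#' @param baseline_schedule,intervention_schedule [schedule_spec()]s; the
#'   defaults are the `"advance"` protocol preset.
#' @param seed Master seed; per-subject series and noise seeds derive
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, true_init_cbt_min = 4,
                        chronotype_sd = 0, obs_noise_sd = 0.25,
                        baseline_schedule = NULL,
                        intervention_schedule = NULL, seed = 1) {
  stopifnot(n_subjects >= 1, chronotype_sd >= 0, obs_noise_sd >= 0)
  if (is.null(baseline_schedule) || is.null(intervention_schedule)) {
    preset <- protocol_preset("advance", seed = seed)
    baseline_schedule <- baseline_schedule %||% preset$baseline
    intervention_schedule <- intervention_schedule %||% preset$intervention
  }
  structure(list(n_subjects = n_subjects,
                 true_init_cbt_min = parse_clock(true_init_cbt_min),
                 chronotype_sd = chronotype_sd,
                 obs_noise_sd = obs_noise_sd,
                 baseline_schedule = baseline_schedule,
                 intervention_schedule = intervention_schedule,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with model-truth observations
#'
#' For each subject: a chronotype (initial CBT_min) is drawn from
#' `N(true_init_cbt_min, chronotype_sd)`; subject-specific baseline and
#' intervention light series are generated; the pacemaker model itself is
#' run over them (continuous chaining from the drawn initial phase) to
#' obtain the true baseline and post-intervention DLMOs; and the
#' "observed" post DLMO is the true one plus Gaussian noise of SD
#' `obs_noise_sd` (so the observed DLMO shift is the model-truth shift
#' plus that noise). Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param cfg The [model_config()] used to generate the truth.
#' @param options [solver_options()].
#' @return List of [subject_record()]s, with each subject's true initial
#'   CBT_min and true shift attached as attributes `true_init` and
#'   `true_delta`.
#' @export
generate_cohort <- function(spec, cfg = model_config(),
                            options = solver_options()) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- with_local_seed(spec$seed,
    sample.int(.Machine$integer.max, spec$n_subjects * 3))
  lapply(seq_len(spec$n_subjects), function(i) {
    chrono <- with_local_seed(seeds[3 * i - 2],
      (spec$true_init_cbt_min + stats::rnorm(1, 0, spec$chronotype_sd)) %% 24)
    bs <- spec$baseline_schedule; bs$seed <- seeds[3 * i - 1]
    is_ <- spec$intervention_schedule; is_$seed <- seeds[3 * i - 1] + 1L
    base_ser <- generate_series(bs)
    int_ser <- generate_series(is_)
    subj <- subject_record(sprintf("S%02d", i), base_ser, int_ser,
                           observed_baseline_dlmo = 0,
                           observed_post_dlmo = 0)
    truth <- predict_delta_dlmo(subj, cfg, init_cbt_min = chrono,
                                chaining = "continuous", options = options,
                                details = TRUE)
    noise <- with_local_seed(seeds[3 * i],
                             stats::rnorm(1, 0, spec$obs_noise_sd))
    subj$observed_baseline_dlmo <- truth$baseline_dlmo
    subj$observed_post_dlmo <- (truth$post_dlmo + noise) %% 24
    attr(subj, "true_init") <- chrono
    attr(subj, "true_delta") <- truth$delta_dlmo
    subj
  })
}
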