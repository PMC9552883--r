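# Per-subject DLMO-shift prediction and the cohort evaluation machinery:
# accuracy metrics, initial-phase sweeps, light-window masking, and model
# parameter sweeps.

#' One subject's light data and observed DLMOs
#'
#' @param subject_id Identifier.
#' @param baseline_series,intervention_series [light_series()] objects for
#'   the baseline and intervention segments. The intervention segment is
#'   assumed to follow the baseline in absolute time.
#' @param observed_baseline_dlmo,observed_post_dlmo Observed DLMO clock
#'   times (decimal hours or `"HH:MM"`), assessed on the last night of
#'   each segment.
#' @param chronotype Optional tag (`"lark"`, `"owl"` or `"none"`).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, baseline_series, intervention_series,
                           observed_baseline_dlmo, observed_post_dlmo,
                           chronotype = "none") {
  stopifnot(inherits(baseline_series, "light_series"),
            inherits(intervention_series, "light_series"),
            nrow(baseline_series) > 0, nrow(intervention_series) > 0)
  b <- parse_clock(observed_baseline_dlmo)
  p <- parse_clock(observed_post_dlmo)
  stopifnot(b >= 0, b < 24, p >= 0, p < 24)
  structure(list(subject_id = subject_id,
                 baseline_series = baseline_series,
                 intervention_series = intervention_series,
                 observed_baseline_dlmo = b,
                 observed_post_dlmo = p,
                 chronotype = chronotype),
            class = "subject_record")
}

#' Predict a subject's DLMO shift from light exposure
#'
#' Implements the baseline-to-intervention chaining: the oscillator is
#' initialized on the dim-light limit cycle at `init_cbt_min`, propagated
#' through the baseline light series, and the last complete CBT_min (and
#' its DLMO) of the baseline segment defines the predicted baseline
#' phase. Integration then continues through the intervention series
#' (either continuously from the end-of-baseline state, or re-initialized
#' on the limit cycle at the end-of-baseline CBT_min), and the last
#' complete DLMO of the intervention segment is the predicted
#' post-intervention phase. The returned shift is
#' `delta_phase(post, baseline)` in (-12, 12]: positive = delay,
#' negative = advance.
#'
#' @param subject A [subject_record()].
#' @param cfg A [model_config()]; both series are first expressed in
#'   `cfg$input_unit`.
#' @param init_cbt_min Assumed CBT_min clock time at the start of
#'   baseline (default `4` = 0400).
#' @param chaining `"continuous"` carries the end-of-baseline state into
#'   the intervention integration; `"reinitialize"` restarts on the limit
#'   cycle at the predicted end-of-baseline CBT_min. The two agree to
#'   within about 0.1 h.
#' @param options [solver_options()].
#' @param details If `TRUE`, return a list with the predicted marker sets
#'   and DLMOs as well as the shift.
#' @return Predicted DLMO shift in hours (or a detail list).
#' @export
predict_delta_dlmo <- function(subject, cfg = model_config(),
                               init_cbt_min = 4,
                               chaining = c("continuous", "reinitialize"),
                               options = solver_options(),
                               details = FALSE) {
  stopifnot(inherits(subject, "subject_record"))
  chaining <- match.arg(chaining)
  init_cbt_min <- parse_clock(init_cbt_min)

  base_drive <- prepare_drive_series(subject$baseline_series,
                                     cfg$input_unit, cfg$cs_params)
  int_drive <- prepare_drive_series(subject$intervention_series,
                                    cfg$input_unit, cfg$cs_params)
  t0 <- subject$baseline_series$time[1]
  s0 <- initialize_from_cbt_min(init_cbt_min, cfg,
                                initial_light = base_drive$series$value[1],
                                t0 = t0)
  traj_b <- integrate_pacemaker(s0, base_drive, cfg, options = options)
  mk_b <- find_cbt_min(traj_b, cfg)
  nb <- nrow(mk_b)
  base_cbt <- mk_b$cbt_min_clock[nb]
  base_dlmo <- mk_b$dlmo_clock[nb]

  if (chaining == "continuous") {
    s1 <- .final_state(traj_b)
  } else {
    s1 <- initialize_from_cbt_min(base_cbt, cfg,
                                  initial_light = int_drive$series$value[1],
                                  t0 = subject$intervention_series$time[1])
  }
  traj_i <- integrate_pacemaker(s1, int_drive, cfg, options = options)
  mk_i <- find_cbt_min(traj_i, cfg)
  ni <- nrow(mk_i)
  post_dlmo <- mk_i$dlmo_clock[ni]

  shift <- delta_phase(post_dlmo, base_dlmo)
  if (!details) return(shift)
  list(delta_dlmo = shift,
       baseline_dlmo = base_dlmo, post_dlmo = post_dlmo,
       baseline_markers = mk_b, intervention_markers = mk_i)
}

#' Cohort-level prediction accuracy
#'
#' Runs [predict_delta_dlmo()] for every subject and compares the
#' predicted shift with the observed shift
#' `delta_phase(observed_post, observed_baseline)`. Per-subject error is
#' the wrapped signed difference predicted - observed; the report gives
#' the mean absolute error (MAE, hours), the percentage of subjects with
#' absolute error below 1 h, and R-squared (squared Pearson correlation
#' of predicted vs observed shifts; `NA` when fewer than two subjects or
#' when either side has zero variance).
#'
#' @param subjects List of [subject_record()]s.
#' @param cfg A [model_config()].
#' @param init_cbt_min Assumed baseline CBT_min clock time.
#' @param chaining,options Passed to [predict_delta_dlmo()].
#' @return An `accuracy_report`: list with `mae`, `pct_within_1h`, `r2`,
#'   `n_subjects`, and a `per_subject` data frame.
#' @export
evaluate_cohort <- function(subjects, cfg = model_config(), init_cbt_min = 4,
                            chaining = "continuous",
                            options = solver_options()) {
  stopifnot(length(subjects) >= 1)
  pred <- vapply(subjects, predict_delta_dlmo, numeric(1),
                 cfg = cfg, init_cbt_min = init_cbt_min,
                 chaining = chaining, options = options)
  obs <- vapply(subjects, function(s)
    delta_phase(s$observed_post_dlmo, s$observed_baseline_dlmo), numeric(1))
  err <- wrap_signed(pred - obs, 24)
  n <- length(err)
  r2 <- if (n >= 2 && stats::sd(pred) > 0 && stats::sd(obs) > 0)
    stats::cor(pred, obs)^2 else NA_real_
  structure(list(
    mae = mean(abs(err)),
    pct_within_1h = 100 * mean(abs(err) < 1),
    r2 = r2,
    n_subjects = n,
    per_subject = data.frame(
      subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
      predicted = pred, observed = obs, error = err)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> n = %d | MAE = %.2f h | %.0f%% within 1 h | R2 = %s\n",
    x$n_subjects, x$mae, x$pct_within_1h,
    if (is.na(x$r2)) "NA" else sprintf("%.2f", x$r2)))
  invisible(x)
}

#' Sweep the assumed initial CBT_min
#'
#' Evaluates the cohort at each initial CBT_min on the grid (default
#' 0300-0900 in 1-h steps) and selects the optimum: the time with the
#' highest percentage of subjects within 1 h, ties broken by lower MAE,
#' then by earlier clock time.
#'
#' @param subjects List of [subject_record()]s.
#' @param cfg A [model_config()].
#' Accuracies are compared after rounding (MAE to 1e-6 h) so that
#' floating-point noise between scientifically identical reports cannot
#' masquerade as a preference; exact ties fall to the earlier time.
#'
#' @param grid Clock times (hours) to test.
#' @param ... Passed to [evaluate_cohort()].
#' @return A list with `table` (data frame `init_cbt_min`, `mae`,
#'   `pct_within_1h`, `r2`), `optimum` (clock hours) and `reports` (the
#'   full `accuracy_report` per grid point).
#' @export
sweep_init_cbt_min <- function(subjects, cfg = model_config(),
                               grid = 3:9, ...) {
  stopifnot(length(grid) >= 1)
  grid <- parse_clock(grid)
  reports <- lapply(grid, function(g)
    evaluate_cohort(subjects, cfg, init_cbt_min = g, ...))
  tab <- data.frame(
    init_cbt_min = grid,
    mae = vapply(reports, `[[`, numeric(1), "mae"),
    pct_within_1h = vapply(reports, `[[`, numeric(1), "pct_within_1h"),
    r2 = vapply(reports, `[[`, numeric(1), "r2"))
  o <- order(-round(tab$pct_within_1h, 9), round(tab$mae, 6),
             tab$init_cbt_min)
  list(table = tab, optimum = tab$init_cbt_min[o[1]], reports = reports)
}

#' Mask a light series to a daily clock window
#'
#' Sets values outside the daily clock window `[start, end)` to zero,
#' leaving timestamps unchanged. Windows wrapping midnight (`start >
#' end`) are supported, and split windows are obtained by composing calls
#' and taking the elementwise maximum implicit in successive masking
#' (each call only zeroes outside its own window, so compose by masking a
#' copy per window and summing -- see examples). A `[0, 24)` window is
#' the identity.
#'
#' @param series A [light_series()].
#' @param window_start,window_end Clock hours in `[0, 24)`.
#' @return The masked `light_series`.
#' @examples
#' s <- light_series(seq(0, 47.9, by = 0.1), rep(0.4, 480), unit = "cs")
#' morning <- mask_light_window(s, 6, 10)      # nonzero 4 h/day
#' # split window 0600-0800 plus 1800-2000:
#' both <- mask_light_window(s, 6, 8)
#' both$value <- pmax(both$value, mask_light_window(s, 18, 20)$value)
#' @export
mask_light_window <- function(series, window_start, window_end) {
  stopifnot(inherits(series, "light_series"))
  ws <- parse_clock(window_start); we <- parse_clock(window_end)
  if (window_end == 24) we <- 24  # full-day window 0-24 is the identity
  clock <- series$time %% 24
  inside <- if (ws <= we) clock >= ws & clock < we
            else clock >= ws | clock < we
  out <- series
  out$value[!inside] <- 0
  out
}

#' Sweep model parameters over their published validation ranges
#'
#' Evaluates cohort accuracy on a grid over one or more of the tunable
#' parameters (`alpha0`, `beta`, `p`, `mu`, `q`, `k`). The gain `G`
#' (derived from `alpha0` and `beta` in the original formulation) and the
#' saturation constant `I0` (an asymptote) are not sweepable. Grid values
#' outside the published validation ranges (`alpha0` 0.01-0.19, `beta`
#' 0.0025-0.02, `p` 0.1-1.0, `mu` 0.01-0.30, `q` 0.15-1.00, `k`
#' 0.15-0.95) are rejected unless `allow_outside_range = TRUE`.
#'
#' @param subjects List of [subject_record()]s.
#' @param cfg Base [model_config()]; swept parameters override its values
#'   point by point.
#' @param grid_spec Named list of numeric vectors, e.g.
#'   `list(alpha0 = c(0.03, 0.05), beta = c(0.005, 0.0075))`; the full
#'   factorial grid is evaluated.
#' @param allow_outside_range Permit values outside the published ranges.
#' @param ... Passed to [evaluate_cohort()].
#' @return A long-format data frame with one row per grid point: the
#'   parameter values plus `mae`, `pct_within_1h`, `r2`.
#' @export
parameter_sweep <- function(subjects, cfg = model_config(), grid_spec,
                            allow_outside_range = FALSE, ...) {
  stopifnot(is.list(grid_spec), length(grid_spec) >= 1,
            !is.null(names(grid_spec)))
  bad <- setdiff(names(grid_spec), names(PARAM_RANGES))
  if (length(bad))
    stop(sprintf("parameter(s) not sweepable: %s (G and I0 are fixed)",
                 toString(bad)))
  if (!allow_outside_range) {
    for (nm in names(grid_spec)) {
      r <- PARAM_RANGES[[nm]]
      v <- grid_spec[[nm]]
      if (any(v < r[1] - 1e-12) || any(v > r[2] + 1e-12))
        stop(sprintf(
          "values for '%s' outside the published range [%g, %g]; set allow_outside_range = TRUE to override",
          nm, r[1], r[2]))
    }
  }
  grid <- expand.grid(grid_spec, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    for (nm in names(grid)) cfg_i[[nm]] <- grid[[nm]][i]
    rep_i <- evaluate_cohort(subjects, cfg_i, ...)
    c(mae = rep_i$mae, pct_within_1h = rep_i$pct_within_1h, r2 = rep_i$r2)
  })
  cbind(grid, do.call(rbind, res))
}

#' Read and write cohort manifests
#'
#' A cohort manifest is a CSV with columns `subject_id`, `baseline_file`,
#' `intervention_file`, `obs_baseline_dlmo`, `obs_post_dlmo`,
#' `chronotype`; light-series file paths are resolved relative to the
#' manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param cohort List of [subject_record()]s to write.
#' @param dir Output directory (created if needed); one light CSV per
#'   segment per subject is written alongside the manifest.
#' @return `read_cohort_manifest()` returns a list of `subject_record`s;
#'   `write_cohort()` returns the manifest path invisibly.
#' @export
read_cohort_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "baseline_file", "intervention_file",
            "obs_baseline_dlmo", "obs_post_dlmo")
  if (!all(need %in% names(df)))
    stop("cohort manifest is missing required columns")
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    subject_record(
      subject_id = as.character(df$subject_id[i]),
      baseline_series = read_light_csv(file.path(base, df$baseline_file[i])),
      intervention_series = read_light_csv(file.path(base, df$intervention_file[i])),
      observed_baseline_dlmo = df$obs_baseline_dlmo[i],
      observed_post_dlmo = df$obs_post_dlmo[i],
      chronotype = if ("chronotype" %in% names(df))
        as.character(df$chronotype[i]) else "none")
  })
}

#' @rdname read_cohort_manifest
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    bf <- sprintf("%s_baseline.csv", s$subject_id)
    i_f <- sprintf("%s_intervention.csv", s$subject_id)
    write_light_csv(s$baseline_series, file.path(dir, bf), s$subject_id)
    write_light_csv(s$intervention_series, file.path(dir, i_f), s$subject_id)
    data.frame(subject_id = s$subject_id, baseline_file = bf,
               intervention_file = i_f,
               obs_baseline_dlmo = s$observed_baseline_dlmo,
               obs_post_dlmo = s$observed_post_dlmo,
               chronotype = s$chronotype)
  })
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an accuracy report to JSON or CSV
#' @param report An `accuracy_report`.
#' @param path Destination (`.json` writes the summary plus per-subject
#'   table; `.csv` writes the per-subject table with summary columns).
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(mae = report$mae, pct_within_1h = report$pct_within_1h,
           r2 = report$r2, n_subjects = report$n_subjects,
           per_subject = report$per_subject),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  } else {
    df <- report$per_subject
    df$mae <- report$mae
    df$pct_within_1h <- report$pct_within_1h
    df$r2 <- report$r2
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
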