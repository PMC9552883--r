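# Subject-level prediction, cohort metrics, masking, and sweeps.

cfg <- model_config()

# small shared cohort: 2-day segments keep these tests quick
small_pre <- protocol_preset("advance", n_days_baseline = 2,
                             n_days_intervention = 2, seed = 31)
small_cohort <- generate_cohort(
  cohort_spec(n_subjects = 3, true_init_cbt_min = 4, chronotype_sd = 0,
              obs_noise_sd = 0, baseline_schedule = small_pre$baseline,
              intervention_schedule = small_pre$intervention, seed = 31),
  cfg)

test_that("an unchanged entraining schedule predicts no DLMO shift", {
  sched <- schedule_spec(n_days = 4, day_level_sigma = 0, seed = 1)
  sched2 <- sched; sched2$start_day <- 4
  subj <- subject_record("S1", generate_series(sched), generate_series(sched2),
                         21, 21)
  shift <- predict_delta_dlmo(subj, cfg, init_cbt_min = 4)
  expect_lt(abs(shift), 0.1)
})

test_that("a morning blue-light advance protocol predicts an advance", {
  pre <- protocol_preset("advance", seed = 13)
  subj <- subject_record("S1", generate_series(pre$baseline),
                         generate_series(pre$intervention), 21, 19)
  shift <- predict_delta_dlmo(subj, cfg, init_cbt_min = 4)
  expect_lt(shift, 0)   # negative = advance
})

test_that("predictions are self-consistent on model-generated subjects", {
  # observations generated by the model itself, zero noise, same settings
  rep0 <- evaluate_cohort(small_cohort, cfg, init_cbt_min = 4)
  expect_lt(rep0$mae, 0.05)
  expect_equal(rep0$pct_within_1h, 100)
})

test_that("continuous and re-initialized chaining agree", {
  # full-length 5-day baseline: the oscillator is near-stationary by the
  # last baseline night, which is what makes the two chaining modes
  # interchangeable
  pre <- protocol_preset("advance", seed = 31)
  s <- subject_record("S1", generate_series(pre$baseline),
                      generate_series(pre$intervention), 21, 20)
  d1 <- predict_delta_dlmo(s, cfg, init_cbt_min = 4, chaining = "continuous")
  d2 <- predict_delta_dlmo(s, cfg, init_cbt_min = 4, chaining = "reinitialize")
  expect_lt(abs(d1 - d2), 0.1)
})

test_that("cohort metrics follow their definitions", {
  # four subjects sharing one light record; observations set so the
  # signed errors are exactly {0.5, -0.5, 1.5, 0}
  s <- small_cohort[[1]]
  p <- predict_delta_dlmo(s, cfg, init_cbt_min = 4)
  errs <- c(0.5, -0.5, 1.5, 0)
  subjects <- lapply(errs, function(e) {
    subject_record(sprintf("E%.1f", e), s$baseline_series,
                   s$intervention_series,
                   observed_baseline_dlmo = 21,
                   observed_post_dlmo = (21 + p - e) %% 24)
  })
  rep_ <- evaluate_cohort(subjects, cfg, init_cbt_min = 4)
  expect_equal(rep_$mae, 0.625, tolerance = 1e-9)
  expect_equal(rep_$pct_within_1h, 75)
  expect_equal(rep_$per_subject$error, errs, tolerance = 1e-9)
  # identical predictions have zero variance: R2 undefined, not 0
  expect_true(is.na(rep_$r2))
  # a single subject never yields an R2
  expect_true(is.na(evaluate_cohort(subjects[1], cfg, init_cbt_min = 4)$r2))
})

test_that("perfect predictions give mae 0, pct 100 and r2 1", {
  subjects <- lapply(small_cohort, function(s) {
    d <- predict_delta_dlmo(s, cfg, init_cbt_min = 4, details = TRUE)
    s$observed_baseline_dlmo <- d$baseline_dlmo
    s$observed_post_dlmo <- d$post_dlmo
    s
  })
  rep_ <- evaluate_cohort(subjects, cfg, init_cbt_min = 4)
  expect_lt(rep_$mae, 1e-9)
  expect_equal(rep_$pct_within_1h, 100)
  expect_equal(rep_$r2, 1, tolerance = 1e-6)
})

test_that("cohort evaluation is permutation-invariant", {
  r1 <- evaluate_cohort(small_cohort, cfg, init_cbt_min = 5)
  r2 <- evaluate_cohort(rev(small_cohort), cfg, init_cbt_min = 5)
  expect_equal(r1$mae, r2$mae)
  expect_equal(r1$pct_within_1h, r2$pct_within_1h)
  expect_equal(r1$r2, r2$r2)
})

test_that("window masking zeroes exactly the out-of-window samples", {
  s <- light_series(seq(0, 48 - 0.05, by = 0.05), rep(0.4, 960), unit = "cs")
  m <- mask_light_window(s, 6, 10)
  clock <- m$time %% 24
  expect_true(all(m$value[clock >= 6 & clock < 10] == 0.4))
  expect_true(all(m$value[clock < 6 | clock >= 10] == 0))
  expect_equal(sum(m$value > 0) / 2, 4 / 0.05)  # 4 h/day
  # full-day mask is the identity
  expect_equal(mask_light_window(s, 0, 24)$value, s$value)
  # composed split windows are disjoint and total 4 h/day
  m1 <- mask_light_window(s, 6, 8)
  m2 <- mask_light_window(s, 18, 20)
  both <- m1; both$value <- pmax(m1$value, m2$value)
  expect_equal(sum(both$value > 0) / 2, 4 / 0.05)
  expect_true(all(!(m1$value > 0 & m2$value > 0)))
  # midnight-wrapping window
  mw <- mask_light_window(s, 22, 2)
  expect_true(all(mw$value[clock >= 2 & clock < 22] == 0))
})

test_that("an all-dark cohort makes every initial phase equivalent", {
  s <- small_cohort[[1]]
  s$baseline_series$value[] <- 0
  s$intervention_series$value[] <- 0
  sw <- sweep_init_cbt_min(list(s), cfg, grid = 3:6)
  # dark free-run: identical accuracy everywhere, tie broken by earliest
  expect_true(all(abs(sw$table$mae - sw$table$mae[1]) < 1e-6))
  expect_equal(sw$optimum, 3)
})

test_that("zero-noise cohorts recover the generating chronotype", {
  pre <- protocol_preset("advance", seed = 17)
  coh <- generate_cohort(
    cohort_spec(n_subjects = 2, true_init_cbt_min = 5, chronotype_sd = 0,
                obs_noise_sd = 0, baseline_schedule = pre$baseline,
                intervention_schedule = pre$intervention, seed = 17), cfg)
  sw <- sweep_init_cbt_min(coh, cfg, grid = 3:9)
  expect_equal(sw$optimum, 5)
  expect_lt(min(sw$table$mae), 1e-6)
})

test_that("parameter sweeps respect the published ranges and reduce to the point evaluation", {
  ref <- evaluate_cohort(small_cohort, cfg, init_cbt_min = 4)
  surf <- parameter_sweep(small_cohort, cfg,
                          list(alpha0 = 0.05, beta = 0.0075),
                          init_cbt_min = 4)
  expect_equal(nrow(surf), 1L)
  expect_equal(surf$mae, ref$mae)
  expect_equal(surf$pct_within_1h, ref$pct_within_1h)
  # a 2 x 2 factorial produces the full grid with finite accuracies
  surf2 <- parameter_sweep(small_cohort, cfg,
                           list(mu = c(0.10, 0.13), q = c(0.33, 0.5)),
                           init_cbt_min = 4)
  expect_equal(nrow(surf2), 4L)
  expect_true(all(is.finite(surf2$mae)))
  # guards: out-of-range values and non-sweepable parameters
  expect_error(parameter_sweep(small_cohort, cfg, list(alpha0 = 0.5)),
               "published range")
  expect_error(parameter_sweep(small_cohort, cfg, list(G = 30)),
               "not sweepable")
  expect_silent(
    parameter_sweep(small_cohort, cfg, list(p = 0.6), init_cbt_min = 4,
                    allow_outside_range = TRUE))
})

test_that("accuracy reports serialize to JSON and CSV", {
  rep_ <- evaluate_cohort(small_cohort, cfg, init_cbt_min = 4)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_accuracy_report(rep_, jp)
  write_accuracy_report(rep_, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$mae, rep_$mae, tolerance = 1e-9)
  expect_equal(nrow(utils::read.csv(cp)), rep_$n_subjects)
})
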