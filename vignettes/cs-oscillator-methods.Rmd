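---
title: "Methods: the CS-driven circadian pacemaker model and its evaluation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CS-driven circadian pacemaker model and its evaluation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csoscillator)
```

## The model

`csoscillator` simulates the human circadian pacemaker as a van der
Pol-type limit-cycle oscillator (Process P) driven by a dynamic
light-stimulus processor (Process L), with the circadian stimulus (CS) —
a saturating, retinally grounded transform of circadian light (CL_A) —
as the default photic input. The state is `(x, x_c, n)`: the two
oscillator variables and the used fraction of Process L's
photoreceptor-element pool. The full equations and the published
parameter set are given on `?model_config`; briefly,

* light `I` (in the configured drive unit) activates ready elements at
  rate $\alpha(I) = \alpha_0 (I/I_0)^p$ per minute and used elements
  recover at rate $\beta$, giving
  $\dot n = 60[\alpha(I)(1-n) - \beta n]$ per hour;
* the photic drive is $\hat B = G\,\alpha(I)(1-n)$, optionally scaled by
  the sensitivity modulator $(1-0.4x)(1-0.4x_c)$ so that the same light
  is more effective at some circadian phases than others;
* Process P is a van der Pol oscillator with a seventh-order
  amplitude-stabilizing term, drive coupling into both state variables
  (`q`, `k`), and an intrinsic period `tau_x` (default 24.2 h); the
  fixed factor 0.99669 makes the simulated dark period equal `tau_x`.

The model's phase marker is the time of the minimum of `x`, interpreted
as CBT_min; DLMO is obtained at a fixed offset (`dlmo_offset`, default
7 h, so DLMO = CBT_min − 7 h). All phase differences are wrapped to
(−12, 12] hours with delays positive. An optional
`xmin_to_cbtmin_lag` (default 0, range 0–2 h) absorbs the alternative
convention in which CBT_min trails the `x` minimum by a fixed amount.

Assumptions worth stating explicitly: light is the only zeitgeber (no
non-photic drive); the CBT_min→DLMO offset is constant across subjects
and conditions; a subject's chronotype enters only through the initial
CBT_min clock time; and the CS transform's constants (asymptote 0.7,
half-saturation 355.7, steepness 1.1026) describe the original CS
calibration — they are configuration values in `cs_params()`, so an
alternative calibration of the same functional form can be substituted.

## Input representations and units

Three drive units are supported, each paired with its saturation
constant: lux (`I0` = 9500), CL_A (`I0` = 9500) and CS (`I0` = the
asymptote, 0.7). `prepare_drive_series()` performs the only computable
conversions (identity mappings, and CL_A → CS through the sigmoid);
lux → CL_A/CS requires spectral information a photopic number does not
carry and is rejected, as is un-compressing CS back to CL_A. With CS
input the ratio `I/I0` entering Process L is bounded in [0, 1).

## Numerical choices

**Integrator.** Light from a wearable logger is a step function: the
recorded value holds until the next sample (zero-order hold, ZOH). The
trajectory integrator is a classical fixed-step Runge–Kutta 4 whose
substeps are aligned to the light-sample boundaries, with substep length
`min(max_step, sampling interval)` (`max_step` default 0.1 h, which also
sets the 6-min output resolution). Alignment matters more than
adaptivity here: the ODE is smooth and slow within a segment (RK4 at
6-min steps is effectively exact for it), while any step that straddles
a light discontinuity injects an O(h·ΔB) error that no error estimator
controls well. The tests verify the integrator against a 0.5-s
forward-Euler brute-force oracle over five days of synthetic logger data
(agreement in `x` better than 10⁻³) and against an adaptive RK4(5)
reference solution on dark segments.

**Gap handling.** Series gaps up to `max_gap` (default 0.25 h) hold the
last recorded value; longer gaps are filled with darkness and a warning
is issued — a conservative, auditable rule for logger dropouts.

**Pool clipping and divergence guard.** `n` is clipped to [0, 1] after
each substep (excursions are at solver-tolerance level). Integration
aborts if `|x|` or `|x_c|` exceeds `divergence_limit` (default 5): the
limit cycle has amplitude ≈ 1, so larger values indicate the run has
left the physically meaningful regime (see Limitations).

**Marker extraction.** CBT_min times are strict local minima of `x`
refined by quadratic interpolation through the three neighbouring
samples; a candidate must be the lowest point within ±6 h, which rejects
small drive-induced wiggles and guarantees one marker per circadian
cycle. Trajectories shorter than one cycle, or without an interior
minimum, raise an insufficient-span error rather than returning a
guess.

**Limit-cycle initialization.** `initialize_from_cbt_min()` places the
state on the dim-light limit cycle so the next `x` minimum falls at the
requested clock time. The cycle is computed once per Process P parameter
set — 95 dark cycles of burn-in at a 6-min step, then five cycles
recorded at 1-min resolution from which the final full cycle is
tabulated by phase — and cached for the session. The Process L pool
starts at its fixed point $\alpha(I_{init})/(\alpha+\beta)$, zero in
darkness.

**Tie-breaks.** The initial-phase sweep selects the grid time with the
highest percentage of subjects within 1 h, ties broken by lower MAE and
then by earlier clock time; MAE values are compared after rounding to
10⁻⁶ h so floating-point noise between scientifically identical reports
cannot masquerade as a preference.

## The evaluation machinery

`predict_delta_dlmo()` follows the baseline→intervention chaining used
in field evaluations: initialize at an assumed CBT_min, integrate the
baseline series, take the last complete baseline DLMO as the predicted
baseline phase, continue through the intervention series, and difference
the last intervention DLMO against baseline. Two chaining modes are
provided — carrying the end-of-baseline state forward (default) or
re-initializing on the limit cycle at the end-of-baseline CBT_min. They
agree to better than 0.1 h when the oscillator is near-stationary by the
last baseline night (the case under the 5-day-or-longer baselines the
protocols use); with much shorter baselines the re-initialized mode
discards genuine transient convergence and the two can differ by ~1 h.

Per-subject error is the wrapped signed difference of predicted and
observed ΔDLMO — the evaluation deliberately compares shift to shift,
never absolute DLMO times, so a constant offset between model phase and
a subject's melatonin physiology cancels. R² is defined as the squared
Pearson correlation of predicted and observed shifts (undefined — `NA`,
never 0 — for fewer than two subjects or zero variance).
`parameter_sweep()` explores the published validation ranges (α₀
0.01–0.19, β 0.0025–0.02, p 0.1–1.0, μ 0.01–0.30, q 0.15–1.00, k
0.15–0.95); the gain `G` is derived from α₀ and β in the original
formulation and `I0` is an asymptote, so neither is sweepable.

**Phase response curves.** `compute_prc()` delivers `n_cycles` daily
pulses whose midpoints land at a requested circadian phase relative to
the initial CBT_min (phases are circadian times, reduced mod 24 so a
grid shifted by a day reproduces the curve exactly), after a one-cycle
dark lead-in and before a ≥2-cycle dark washout. The shift is measured
against an unstimulated control run sharing every setting except the
pulse, which removes free-run drift exactly — the model's PRC protocol
is not pinned down by the evaluations it reproduces, and the
control-subtraction design was chosen because it needs no assumption
about how many washout cycles suffice for drift-free projection.

## The synthetic-data generator

`generate_series()` emulates a calibrated wearable light logger
(Daysimeter-like): 30–180-s storage intervals, a wake/sleep schedule
with optional day-to-day jitter, darkness during sleep, and timed daily
interventions that overwrite the background level. Daytime light uses a
median level of CS 0.15 — a plausible ordinary indoor exposure; typical
levels were not reported for the field studies being emulated — with
per-sample log-normal multiplicative fluctuation (σ = 0.3 log units),
mirroring the strong short-term variability real loggers record as the
wearer moves around. CS-unit values are clipped at the 0.7 asymptote,
which the physical metric cannot exceed. `protocol_preset()` provides
schedule pairs patterned on four field protocols (morning-blue advance,
evening-blue delay, one-hour morning blue, blue goggles with evening
orange filtering).

`generate_cohort()` draws per-subject chronotypes, generates
subject-specific series, runs the model itself to obtain true DLMOs, and
adds Gaussian noise to the post-intervention DLMO — so the ΔDLMO
observation noise SD equals `obs_noise_sd` exactly, consistent with an
evaluation that operates on shifts rather than absolute times. All
generators are pure functions of their specs (seeds included).

What passing tests on these cohorts do *not* show: synthetic schedules
are far more regular than field data (no weekends, no outdoor
excursions, no compliance lapses), the between-subject variance of true
shifts is small when chronotype spread is zero, and entrainment under a
clean 16-h photoperiod is faster than under ragged field exposure.
Cohort-level accuracy numbers on synthetic data therefore say the
machinery is self-consistent, not that the model attains any particular
accuracy on real cohorts.

## Problem sizes

The test battery uses 20-subject cohorts with 5-day baselines and 7-day
interventions sampled at 180 s, a 5-day integrator-oracle comparison at
a 0.5-s Euler step, a 61-cycle dark run for the free-running period, a
40-day entrainment run, and 24-phase PRCs — sizes chosen so the entire
suite completes in about a minute on one core while still exercising
multi-week integrations.

## Known limitations

* **Process-L bypass under sustained strong drive.** With Process L
  bypassed (`process_l = FALSE`) the drive `G α(I)` is not attenuated by
  the adaptation pool, and the `q B x_c` term acts as anti-damping that
  the sensitivity modulator further amplifies once `x_c` grows. Under
  sustained flat light at CS ≈ 0.3 or more the state grows without
  bound within a day and the divergence guard aborts the run. This is a
  property of the equations, not of the solver; field-like inputs
  (fluctuating, mostly ≤ CS 0.2) stay bounded. Bypass mode is intended
  for ablation comparisons on realistic inputs.
* **Initial-phase recovery at realistic noise.** After a 5-day
  entraining baseline the model retains only ~0.1 h of ΔDLMO bias per
  hour of initial-CBT_min error, so with 0.25-h observation noise the
  sweep's selection between adjacent 1-h grid points is
  noise-dominated on model-generated cohorts; recovery is exact at zero
  noise. Field cohorts, with larger and more structured errors,
  discriminate more sharply.
* No non-photic (sleep/wake) drive; no spectral computation from sensor
  channels (CL_A must be supplied, not derived from lux); melatonin
  concentration profiles and amplitude markers are out of scope.
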