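# Model configuration: Process L / Process P parameters, the CS transform,
# input-unit and component toggles, and solver options.

# Published sweep ranges for the tunable parameters (min, max).
PARAM_RANGES <- list(
  alpha0 = c(0.01, 0.19),
  beta   = c(0.0025, 0.0200),
  p      = c(0.1, 1.0),
  mu     = c(0.01, 0.30),
  q      = c(0.15, 1.00),
  k      = c(0.15, 0.95)
)

#' Pacemaker model configuration
#'
#' Bundles every parameter of the light-driven pacemaker model.
#'
#' Process L (the dynamic stimulus processor) converts light `I` into a
#' neural drive via an activation rate \eqn{\alpha(I) = \alpha_0
#' (I/I_0)^p} (per minute) and a ready/used photoreceptor-element pool
#' with used fraction `n`, \eqn{\dot n = 60[\alpha(I)(1-n) - \beta n]}
#' (per hour). The drive is \eqn{\hat B = G\,\alpha(I)(1-n)}, optionally
#' multiplied by the phase-dependent sensitivity modulator
#' \eqn{(1-0.4x)(1-0.4x_c)}.
#'
#' Process P is the van der Pol-type limit-cycle oscillator
#' \deqn{\dot x   = \frac{\pi}{12}\left[x_c + B + \mu\left(\frac{x}{3}
#'   + \frac{4x^3}{3} - \frac{256 x^7}{105}\right)\right]}
#' \deqn{\dot x_c = \frac{\pi}{12}\left[q B x_c - x\left(
#'   \left(\frac{24}{0.99669\,\tau_x}\right)^2 + k B\right)\right]}
#' whose intrinsic free-running period is `tau_x` (the 0.99669 factor
#' makes the simulated dark period equal `tau_x`).
#'
#' Defaults are the published parameter set: `alpha0 = 0.05`, `beta =
#' 0.0075`, `G = 33.75`, `p = 0.6`, `mu = 0.13`, `q = 0.33`, `k = 0.55`,
#' with `I0` resolved from the input unit (9500 for lux/CL_A, the CS
#' asymptote 0.7 for CS). `tau_x = 24.2` h is the standard intrinsic
#' period for diurnal humans.
#'
#' @param alpha0 Light-activation rate scale, per minute.
#' @param beta Pool recovery rate, per minute.
#' @param G Drive gain (dimensionless; derived from `alpha0`/`beta` in the
#'   original formulation and therefore never swept).
#' @param p Light exponent, in (0, 1].
#' @param I0 Saturation constant in drive units; `NULL` resolves it from
#'   `input_unit`.
#' @param mu Oscillator stiffness.
#' @param q Drive coupling into `x_c`.
#' @param k Drive effect on angular frequency.
#' @param tau_x Intrinsic period in hours, in (18, 30).
#' @param period_correction Fixed period-correction factor 0.99669.
#' @param modulator_coeff Coefficient 0.4 of the sensitivity modulator.
#' @param process_l Include Process L dynamics? `FALSE` bypasses the
#'   adaptation pool (the `(1-n)` term is held at 1) so light feeds
#'   Process P directly as `B = G alpha(I)`.
#' @param modulator Apply the phase-dependent sensitivity modulator?
#' @param input_unit Drive unit the model runs in: `"lux"`, `"cla"`, `"cs"`.
#' @param cs_params [cs_params()] for the CL_A -> CS transform.
#' @param dlmo_offset Hours DLMO precedes CBT_min (default 7).
#' @param xmin_to_cbtmin_lag Hours added to the `x`-minimum time to define
#'   CBT_min (default 0), in `[0, 2]`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(alpha0 = 0.05, beta = 0.0075, G = 33.75, p = 0.6,
                         I0 = NULL, mu = 0.13, q = 0.33, k = 0.55,
                         tau_x = 24.2, period_correction = 0.99669,
                         modulator_coeff = 0.4,
                         process_l = TRUE, modulator = TRUE,
                         input_unit = c("cs", "cla", "lux"),
                         cs_params = csoscillator::cs_params(),
                         dlmo_offset = 7, xmin_to_cbtmin_lag = 0) {
  input_unit <- match.arg(input_unit)
  if (is.null(I0)) I0 <- if (input_unit == "cs") cs_params$asymptote else 9500
  stopifnot(alpha0 > 0, beta > 0, G > 0, p > 0, p <= 1, I0 > 0,
            mu > 0, q > 0, k > 0, tau_x > 18, tau_x < 30,
            period_correction > 0, modulator_coeff >= 0,
            is.logical(process_l), is.logical(modulator),
            dlmo_offset > 0, dlmo_offset < 12,
            xmin_to_cbtmin_lag >= 0, xmin_to_cbtmin_lag <= 2)
  structure(list(
    alpha0 = alpha0, beta = beta, G = G, p = p, I0 = I0,
    mu = mu, q = q, k = k, tau_x = tau_x,
    period_correction = period_correction,
    modulator_coeff = modulator_coeff,
    process_l = process_l, modulator = modulator,
    input_unit = input_unit, cs_params = cs_params,
    dlmo_offset = dlmo_offset,
    xmin_to_cbtmin_lag = xmin_to_cbtmin_lag),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  Process L: alpha0=%.4g beta=%.4g G=%.4g p=%.4g I0=%.4g [%s]\n",
              x$alpha0, x$beta, x$G, x$p, x$I0,
              if (x$process_l) "on" else "bypassed"))
  cat(sprintf("  Process P: mu=%.4g q=%.4g k=%.4g tau_x=%.4g  modulator %s\n",
              x$mu, x$q, x$k, x$tau_x, if (x$modulator) "on" else "off"))
  cat(sprintf("  input unit: %s; DLMO = CBT_min - %g h\n",
              x$input_unit, x$dlmo_offset))
  invisible(x)
}

#' Numerical options for the trajectory integrator
#'
#' The integrator is a classical fixed-step Runge-Kutta 4 whose steps are
#' aligned to the light-sample boundaries (zero-order hold), with substep
#' length `min(max_step, sampling interval)`. `max_step` therefore never
#' exceeds the light-sampling interval, and also sets the trajectory
#' output resolution (default 0.1 h = 6 min). `max_gap` controls gap
#' handling: gaps up to `max_gap` hours hold the last light value; longer
#' gaps are filled with darkness and a warning is issued.
#'
#' @param max_step Maximum integration substep, hours.
#' @param max_gap Longest series gap bridged by holding the last value,
#'   hours.
#' @param divergence_limit Abort when `|x|` or `|x_c|` exceeds this (the
#'   limit cycle has amplitude about 1, so larger values indicate
#'   numerical failure).
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(max_step = 0.1, max_gap = 0.25,
                           divergence_limit = 5) {
  stopifnot(max_step > 0, max_gap > 0, divergence_limit > 1)
  structure(list(max_step = max_step, max_gap = max_gap,
                 divergence_limit = divergence_limit),
            class = "solver_options")
}

#' Serialize and restore a model configuration
#'
#' Configurations are written as JSON or YAML (chosen from the file
#' extension) with the published parameter names (`alpha0`, `beta`, `G`,
#' `p`, `I0`, `mu`, `q`, `k`) plus the toggles (`process_l`, `modulator`,
#' `input_unit`) and the CS-transform constants.
#'
#' @param cfg A [model_config()].
#' @param path Destination/source file (`.json`, `.yaml` or `.yml`).
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `model_config`.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  lst <- unclass(cfg)
  lst$cs_params <- unclass(lst$cs_params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  csp <- do.call(cs_params, lst$cs_params %||% list())
  lst$cs_params <- csp
  do.call(model_config, lst)
}
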