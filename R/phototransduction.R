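# Photic-input representations: lux, circadian light (CL_A) and the
# circadian stimulus (CS) sigmoid, with the saturation constant I0 paired
# to each representation.

#' Parameters of the circadian stimulus (CS) transform
#'
#' The CS transform compresses circadian light (CL_A) into the effective
#' stimulus reaching the SCN:
#' \deqn{CS = A \left[1 - \frac{1}{1 + (CL_A/c_1)^{c_2}}\right]}
#' with response ceiling (asymptote) \eqn{A = 0.7}, half-saturation
#' constant \eqn{c_1 = 355.7} (the CL_A at which the response is half the
#' asymptote) and steepness exponent \eqn{c_2 = 1.1026}. The asymptote is
#' the published ceiling of the CS metric; the sigmoid constants are the
#' original CS-model calibration and are configuration values here, so
#' that alternative calibrations of the same functional form can be used.
#'
#' @param asymptote Response ceiling, in (0, 1]. Default 0.7.
#' @param half_saturation CL_A giving half the asymptote. Default 355.7.
#' @param steepness Dimensionless exponent. Default 1.1026.
#' @return An object of class `cs_params`.
#' @export
cs_params <- function(asymptote = 0.7, half_saturation = 355.7,
                      steepness = 1.1026) {
  stopifnot(asymptote > 0, asymptote <= 1,
            half_saturation > 0, steepness > 0)
  structure(list(asymptote = asymptote,
                 half_saturation = half_saturation,
                 steepness = steepness),
            class = "cs_params")
}

#' Circadian stimulus from circadian light
#'
#' Evaluates the saturating CS sigmoid at the given CL_A value(s). The
#' result is 0 at zero light, strictly increasing, and approaches (never
#' reaches) the asymptote at very high CL_A; at `half_saturation` it is
#' exactly half the asymptote.
#'
#' @param cla Nonnegative CL_A value(s).
#' @param params A [cs_params()] object.
#' @return CS value(s) in `[0, asymptote)`.
#' @examples
#' cs_from_cla(0)      # 0
#' cs_from_cla(355.7)  # 0.35, the sigmoid midpoint
#' cs_from_cla(1e9)    # ~0.70, the asymptote
#' @export
cs_from_cla <- function(cla, params = cs_params()) {
  stopifnot(inherits(params, "cs_params"))
  if (any(!is.finite(cla)) || any(cla < 0))
    stop("cs_from_cla: CL_A must be finite and nonnegative")
  params$asymptote *
    (1 - 1 / (1 + (cla / params$half_saturation)^params$steepness))
}

#' Express a light series in the model's drive units
#'
#' The oscillator's Process L consumes light in one of three
#' representations, each paired with its own saturation constant I0:
#' photopic lux (I0 = 9500), CL_A (I0 = 9500) or CS (I0 = the CS
#' asymptote, 0.7). Valid conversions are the identity mappings and
#' CL_A -> CS via [cs_from_cla()]. Lux cannot be converted to CL_A or CS
#' (that requires spectral information a single photopic number does not
#' carry), and CS cannot be un-compressed back to CL_A here; a series
#' recorded in CS units can only be used in CS mode.
#'
#' @param series A [light_series()].
#' @param mode Requested drive unit: `"lux"`, `"cla"` or `"cs"`.
#' @param params [cs_params()] used for the CL_A -> CS mapping and for the
#'   CS-mode I0.
#' @return A list with elements `series` (a `light_series` in the
#'   requested unit) and `I0` (the paired saturation constant).
#' @export
prepare_drive_series <- function(series, mode = c("lux", "cla", "cs"),
                                 params = cs_params()) {
  stopifnot(inherits(series, "light_series"))
  mode <- match.arg(mode)
  from <- light_unit(series)
  if (from == mode) {
    out <- series
  } else if (from == "cla" && mode == "cs") {
    out <- light_series(series$time, cs_from_cla(series$value, params),
                        unit = "cs", asymptote = params$asymptote)
    attr(out, "subject_id") <- attr(series, "subject_id")
  } else {
    stop(sprintf(
      "unsupported light-unit conversion: '%s' -> '%s' (no spectral information)",
      from, mode))
  }
  I0 <- if (mode == "cs") params$asymptote else 9500
  list(series = out, I0 = I0)
}
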