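# Internal helpers shared across modules.

#' Wrap a signed hour difference into (-12, 12]
#'
#' Computes the circular difference `t1 - t0` between two clock times in
#' hours, wrapped so that the result lies in the half-open interval
#' (-12, 12]. The package-wide sign convention is that positive values are
#' phase delays (`t1` later than `t0`) and negative values are advances.
#' The 12-h antipode maps to +12, never -12.
#'
#' @param t1,t0 Clock times in decimal hours (any real values; reduced
#'   modulo 24). Vectorised.
#' @return Signed difference in hours, in (-12, 12].
#' @examples
#' delta_phase(1, 23)   # +2, wraps across midnight
#' delta_phase(21, 4)   # -7
#' delta_phase(11, 23)  # +12 boundary
#' @export
delta_phase <- function(t1, t0) {
  d <- ((t1 - t0 + 12) %% 24) - 12
  d[d == -12] <- 12
  d
}

# Wrap a difference to (-period/2, period/2] for an arbitrary period.
wrap_signed <- function(d, period) {
  half <- period / 2
  out <- ((d + half) %% period) - half
  out[out == -half] <- half
  out
}

# Parse a clock time given as decimal hours or "HH:MM" into decimal hours.
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  stopifnot(is.character(x))
  vapply(x, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) return(as.numeric(parts) %% 24)
    (as.numeric(parts[1]) + as.numeric(parts[2]) / 60) %% 24
  }, numeric(1), USE.NAMES = FALSE)
}

# Format decimal hours as HH:MM.
format_clock <- function(h) {
  h <- h %% 24
  hh <- floor(h)
  mm <- round((h - hh) * 60)
  hh[mm == 60] <- hh[mm == 60] + 1
  mm[mm == 60] <- 0
  sprintf("%02d:%02d", hh %% 24, mm)
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
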