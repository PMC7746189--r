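#' Piecewise-linear diurnal flux function
#'
#' A diurnal flux modulates a physiological rate over the 24-hour clock:
#' multiplicatively for insulin kinetics (`Im`) and meal absorption (`fm`),
#' additively (in micromol/kg/min) for the glucose flux `Fg`. The flux is a
#' continuous piecewise-linear interpolant through knot (time, value) pairs,
#' periodic with period 1440 min, so the value at midnight wraps smoothly.
#'
#' @param times numeric vector of knot clock times in minutes, strictly
#'   increasing, all within `[0, 1440)`.
#' @param values numeric vector of knot values, same length as `times`.
#' @return an object of class `diurnal_flux`.
#' @examples
#' fl <- diurnal_flux(c(0, 360, 720, 1080), c(1, 1.2, 0.9, 1.1))
#' flux_at(fl, 540)            # linear interpolation between knots
#' flux_at(fl, 540 + 1440)     # periodic: same value next day
#' @export
diurnal_flux <- function(times, values) {
  if (length(times) < 2L)
    stop("a diurnal flux needs at least 2 knots", call. = FALSE)
  if (length(times) != length(values))
    stop("knot times and values must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("flux knots must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("flux knot times must be strictly increasing", call. = FALSE)
  if (times[1L] < 0 || times[length(times)] >= 1440)
    stop("flux knot times must lie in [0, 1440)", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "diurnal_flux")
}

#' Evaluate a diurnal flux at clock time(s)
#'
#' @param flux a [diurnal_flux()].
#' @param t numeric vector of clock times in minutes; reduced modulo 1440.
#' @return numeric vector of flux values.
#' @export
flux_at <- function(flux, t) {
  stopifnot(inherits(flux, "diurnal_flux"))
  tt <- t %% 1440
  n <- length(flux$times)
  # extend one knot past each end so interpolation wraps across midnight
  xs <- c(flux$times[n] - 1440, flux$times, flux$times[1L] + 1440)
  ys <- c(flux$values[n], flux$values, flux$values[1L])
  stats::approx(xs, ys, xout = tt, rule = 1)$y
}

#' Time-average of a diurnal flux over one 24-h cycle
#'
#' Exact integral of the piecewise-linear interpolant divided by 1440; used
#' when titrating basal insulin against the patient's average physiology.
#'
#' @param flux a [diurnal_flux()].
#' @return scalar mean value.
#' @export
flux_mean <- function(flux) {
  n <- length(flux$times)
  xs <- c(flux$times, flux$times[1L] + 1440)
  ys <- c(flux$values, flux$values[1L])
  sum(diff(xs) * (ys[-1L] + ys[-(n + 1L)]) / 2) / 1440
}

#' @export
print.diurnal_flux <- function(x, ...) {
  cat(sprintf("<diurnal_flux> %d knots, mean %.3f\n",
              length(x$times), flux_mean(x)))
  invisible(x)
}

#' Constant flux helper
#'
#' @param value the constant value (default 1, the identity multiplier).
#' @return a [diurnal_flux()] evaluating to `value` everywhere.
#' @export
constant_flux <- function(value = 1) {
  diurnal_flux(c(0, 720), c(value, value))
}

#' Build a diurnal flux from knot times and multipliers
#'
#' Thin constructor matching the cohort generator's interface: knots are
#' typically an equally spaced grid over 24 h with log-normally dispersed
#' multipliers around 1.
#'
#' @param knot_times knot clock times (min in `[0, 1440)`), strictly
#'   increasing.
#' @param multipliers knot values.
#' @return a [diurnal_flux()].
#' @export
build_flux <- function(knot_times, multipliers) {
  diurnal_flux(knot_times, multipliers)
}
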