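#' Uniformly sampled time series
#'
#' Lightweight carrier for sampled signals and concentration curves. All
#' simulation and reconstruction functions in the package consume and return
#' `pdd_ts` objects so that sampling metadata (start time, step, time unit)
#' travels with the values.
#'
#' @param values Numeric vector of samples (length >= 2, finite).
#' @param dt Sampling step, in the unit given by `unit`.
#' @param t0 Time of the first sample (default 0).
#' @param unit Time unit of `dt` and `t0`: `"min"` or `"s"`.
#' @param label Optional channel / compartment identifier.
#' @return An object of class `pdd_ts`.
#' @examples
#' s <- pdd_ts(sin(2 * pi * seq(0, 5, 0.05)), dt = 0.05, unit = "s")
#' ts_time(s)[1:3]
#' @export
pdd_ts <- function(values, dt, t0 = 0, unit = c("min", "s"), label = "") {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a time series needs at least 2 samples")
  if (!all(is.finite(values))) stop("time series values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be a positive number")
  structure(list(values = values, dt = dt, t0 = t0, unit = unit,
                 label = as.character(label)),
            class = "pdd_ts")
}

#' @export
print.pdd_ts <- function(x, ...) {
  cat(sprintf("<pdd_ts> %s: %d samples, dt = %g %s, t0 = %g, range [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$dt, x$unit, x$t0,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.pdd_ts <- function(x) length(x$values)

#' @export
as.data.frame.pdd_ts <- function(x, ...) {
  data.frame(time = ts_time(x), value = x$values)
}

#' Sampling times of a time series
#'
#' @param x A [pdd_ts] object.
#' @return Numeric vector of sample times in `x$unit`.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "pdd_ts"))
  x$t0 + x$dt * (seq_along(x$values) - 1)
}

#' @keywords internal
stop_if_grid_mismatch <- function(a, b) {
  if (!isTRUE(all.equal(a$dt, b$dt)) || a$unit != b$unit ||
      !isTRUE(all.equal(a$t0, b$t0)) || length(a$values) != length(b$values))
    stop("time series are on different sampling grids")
  invisible(NULL)
}

#' Causal discrete convolution on a uniform grid
#'
#' Trapezoidal-rule approximation of the convolution integral
#' `(a * b)(t) = integral a(s) b(t - s) ds` for two sequences sampled at a
#' common step `dt`, truncated to the support of the first input. Computed
#' via FFT (through [stats::convolve]) with end-point trapezoid weights.
#'
#' @param a,b Numeric vectors on the same grid (`b` is the kernel).
#' @param dt Grid step.
#' @param rule `"trapezoid"` (default) or `"rectangle"` (plain Riemann sum).
#' @return Numeric vector, `length(a)` samples of the causal convolution.
#' @export
conv_causal <- function(a, b, dt, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  n <- length(a)
  if (length(b) < n) b <- c(b, rep(0, n - length(b)))
  b <- b[seq_len(n)]
  full <- stats::convolve(a, rev(b), type = "open")[seq_len(n)]
  if (rule == "trapezoid") {
    i <- seq_len(n)
    full <- full - 0.5 * (a[1] * b[i] + a[i] * b[1])
  }
  full * dt
}
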