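#' Compartmental rate constants
#'
#' Rate constants for the tissue kinetic models. `K1` (blood -> tissue) and
#' `k2` (tissue -> blood) govern exchange across the vessel wall; `kon`,
#' `koff` and `Bmax` describe saturable binding of the targeted agent to its
#' receptor pool in the two-compartment tumor model. For an untargeted
#' (control) agent set `kon = 0`, which reduces the tumor model to the
#' one-compartment model.
#'
#' Units: `K1`, `k2`, `koff` in min^-1; `kon` in min^-1 per concentration
#' unit; `Bmax` in concentration units. The binding parameters are applied
#' in the same concentration unit as the plasma input functions, so the
#' degree of receptor saturation is set by the ratio of the free tissue
#' concentration to `koff / kon`.
#'
#' @param K1 Influx rate constant (min^-1, > 0). Default 0.1.
#' @param k2 Efflux rate constant (min^-1, > 0). Default 0.08.
#' @param kon Association rate constant (>= 0). Default 0.05.
#' @param koff Dissociation rate constant (min^-1, >= 0). Default 0.12.
#' @param Bmax Available receptor concentration (>= 0). Default 10.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1 = 0.1, k2 = 0.08, kon = 0.05, koff = 0.12,
                           Bmax = 10) {
  if (!is.finite(K1) || K1 < 0) stop("'K1' must be >= 0")
  if (!is.finite(k2) || k2 <= 0) stop("'k2' must be > 0")
  if (!is.finite(kon) || kon < 0) stop("'kon' must be >= 0")
  if (!is.finite(koff) || koff < 0) stop("'koff' must be >= 0")
  if (!is.finite(Bmax) || Bmax < 0) stop("'Bmax' must be >= 0")
  structure(list(K1 = K1, k2 = k2, kon = kon, koff = koff, Bmax = Bmax),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> K1=%g k2=%g min^-1, kon=%g koff=%g Bmax=%g\n",
              x$K1, x$k2, x$kon, x$koff, x$Bmax))
  invisible(x)
}

#' One-compartment tissue concentration
#'
#' Concentration of an agent in well-mixed extravascular tissue driven by
#' its plasma curve: `dCf/dt = K1 Cp(t) - k2 Cf(t)`, equivalently
#' `Cf(t) = K1 Cp(t) * (u(t) exp(-k2 t))` with `*` convolution and `u` the
#' unit step. For a bi-exponential plasma curve the convolution is evaluated
#' in closed form; for a sampled [pdd_ts] input a trapezoidal discrete
#' convolution is used.
#'
#' @param pif A [biexp_pif] or a [pdd_ts] plasma curve (time unit minutes).
#' @param kp A [kinetic_params]; `kon`, `koff`, `Bmax` are ignored.
#' @param t Uniform non-negative time grid (min). Ignored when `pif` is a
#'   [pdd_ts] (its own grid is used).
#' @return A [pdd_ts] of tissue concentrations; `Cf(0) = 0`.
#' @export
one_compartment <- function(pif, kp, t = NULL) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (inherits(pif, "biexp_pif")) {
    if (is.null(t)) stop("'t' is required for a bi-exponential input")
    t <- as.numeric(t)
    if (any(t < 0)) stop("time grid must be non-negative")
    dts <- diff(t)
    if (length(t) < 2 || diff(range(dts)) > 1e-9 * max(dts))
      stop("time grid must be uniform")
    v <- kp$K1 * (biexp_lobe(pif$amp1, pif$rate1, kp$k2, t) +
                  biexp_lobe(pif$amp2, pif$rate2, kp$k2, t))
    pdd_ts(v, dt = dts[1], t0 = t[1], unit = "min",
           label = paste0(pif$label, " tissue"))
  } else if (inherits(pif, "pdd_ts")) {
    if (pif$unit != "min") stop("sampled plasma input must be in minutes")
    tt <- ts_time(pif) - pif$t0
    kern <- exp(-kp$k2 * tt)
    v <- kp$K1 * conv_causal(pif$values, kern, pif$dt)
    out <- pif
    out$values <- pmax(v, 0)
    out$label <- paste0(pif$label, " tissue")
    out
  } else stop("'pif' must be a biexp_pif or pdd_ts")
}

# closed-form amp * exp(-r t) convolved with exp(-k2 t), times unity gain
biexp_lobe <- function(amp, r, k2, t) {
  if (abs(k2 - r) < 1e-12) return(amp * t * exp(-k2 * t))
  amp / (k2 - r) * (exp(-r * t) - exp(-k2 * t))
}

#' Two-compartment tumor model with saturable binding
#'
#' Solves the coupled system for free (`Cf`) and receptor-bound (`Cb`)
#' agent in tumor tissue:
#' \deqn{dCf/dt = K1 Cp(t) - k2 Cf - kon (Bmax - Cb) Cf + koff Cb}
#' \deqn{dCb/dt = kon (Bmax - Cb) Cf - koff Cb}
#' using an adaptive Runge-Kutta solver (Dormand-Prince 4(5) via
#' [deSolve::ode], `method = "ode45"`, rtol 1e-8 / atol 1e-10). With
#' `kon = 0` the bound pool stays empty and `Cf` reduces to the
#' one-compartment solution. The bound pool can never exceed `Bmax`.
#'
#' @param pif A [biexp_pif] driving plasma curve.
#' @param kp A [kinetic_params].
#' @param t Uniform non-negative time grid (min), default `0:300`.
#' @return A list with [pdd_ts] components `Cf`, `Cb` and `total`
#'   (`Cf + Cb`, the measurable tissue signal).
#' @export
tumor_model <- function(pif, kp, t = seq(0, 300, by = 1)) {
  stopifnot(inherits(pif, "biexp_pif"), inherits(kp, "kinetic_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("time grid must be non-negative")
  dts <- diff(t)
  if (length(t) < 2 || diff(range(dts)) > 1e-9 * max(dts))
    stop("time grid must be uniform")
  rhs <- function(tt, y, p) {
    cp <- pif$amp1 * exp(-pif$rate1 * tt) + pif$amp2 * exp(-pif$rate2 * tt)
    free <- kp$Bmax - y[2]
    bind <- kp$kon * free * y[1]
    list(c(kp$K1 * cp - kp$k2 * y[1] - bind + kp$koff * y[2],
           bind - kp$koff * y[2]))
  }
  sol <- deSolve::ode(y = c(Cf = 0, Cb = 0), times = t, func = rhs,
                      parms = NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  if (nrow(sol) < length(t))
    stop("tumor model ODE solver failed to integrate the full time grid ",
         "(stopped at t = ", sol[nrow(sol), 1], " min)")
  cf <- pmax(sol[, "Cf"], 0)
  cb <- pmin(pmax(sol[, "Cb"], 0), kp$Bmax)
  mk <- function(v, lab) pdd_ts(v, dt = dts[1], t0 = t[1], unit = "min",
                                label = paste(pif$label, lab))
  list(Cf = mk(cf, "free"), Cb = mk(cb, "bound"), total = mk(cf + cb, "total"))
}
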