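#' Fluorophore optical constants of a detection channel
#'
#' Quantum yield and molar extinction enter the detected-signal model only
#' through their product (a per-channel gain). Because reconstructed plasma
#' curves are normalized to their maximum, the absolute gain cancels
#' downstream; both channels therefore default to a unit product.
#'
#' @param eta Fluorescence quantum yield, in (0, 1].
#' @param epsilon Molar extinction coefficient at peak absorption
#'   (M^-1 cm^-1, > 0).
#' @param channel Channel label, e.g. `"800-band targeted"`.
#' @return An object of class `agent_optics`.
#' @export
agent_optics <- function(eta = 1, epsilon = 1, channel = "") {
  if (!is.finite(eta) || eta <= 0 || eta > 1) stop("'eta' must be in (0, 1]")
  if (!is.finite(epsilon) || epsilon <= 0) stop("'epsilon' must be > 0")
  structure(list(eta = eta, epsilon = epsilon, channel = as.character(channel)),
            class = "agent_optics")
}

#' Detector noise model
#'
#' Describes the detector: dynamic range as bit depth (signal maxima are
#' scaled to the half-maximum count of the detector before shot-noise
#' sampling) and an additive Gaussian component representing the pooled
#' physiological/instrumental noise, expressed relative to the standard
#' deviation of the recorded signal. Calibrate `gauss_sigma_rel` from a
#' measured plethysmography trace with [calibrate_pleth_sigma()]; the
#' default 0.01 is a realistic value for a clinical finger probe.
#'
#' @param bit_depth Integer detector bit depth, 8 to 30 (values above 16
#'   act as an effectively noise-free quantization proxy).
#' @param gauss_sigma_rel Relative SD of the additive Gaussian noise
#'   (>= 0).
#' @param seed Optional integer seed; when given, [add_noise()] is
#'   reproducible and leaves the global RNG state untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(bit_depth = 16L, gauss_sigma_rel = 0.01, seed = NULL) {
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 8L || bit_depth > 30L)
    stop("'bit_depth' must be an integer in 8..30")
  if (!is.finite(gauss_sigma_rel) || gauss_sigma_rel < 0)
    stop("'gauss_sigma_rel' must be >= 0")
  structure(list(bit_depth = bit_depth, gauss_sigma_rel = gauss_sigma_rel,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "noise_model")
}

#' Synthesize the detected fluorescence signal of one channel
#'
#' Implements the detected-signal model
#' `S(t) = Iex eta epsilon [Jart(t) Cp(t) + Jtis(t) Cf(t)]`:
#' the arterial region carries the (cardiac-modulated) plasma concentration
#' and everything outside the vessels carries the one-compartment tissue
#' concentration, each weighted by the ROI-summed adjoint sensitivity. The
#' ROI weights oscillate over the cardiac cycle because vessel dilation
#' changes the blood optical properties; they are interpolated between the
#' two precomputed Monte Carlo states along the same sinusoid as the
#' concentration modulation (volume and concentration in phase by default).
#'
#' @param jac A [sensitivity_states] (two-weight mode or MC-derived) or a
#'   static `sensitivity_map`.
#' @param cp Modulated plasma curve ([pdd_ts], seconds grid at `cfg$dt`),
#'   from [modulate_pif()].
#' @param cf Tissue concentration on the same grid.
#' @param optics An [agent_optics].
#' @param cfg The [pulsatile_config] used for `cp`.
#' @param Iex Excitation intensity (arbitrary units, default 1).
#' @param phase Phase offset (radians) of the volume waveform relative to
#'   the concentration modulation; default 0 (in phase).
#' @return A [pdd_ts] of detected signal (arbitrary units, >= 0).
#' @export
synthesize_signal <- function(jac, cp, cf, optics = agent_optics(),
                              cfg = pulsatile_config(), Iex = 1, phase = 0) {
  stopifnot(inherits(cp, "pdd_ts"), inherits(cf, "pdd_ts"),
            inherits(optics, "agent_optics"), inherits(cfg, "pulsatile_config"))
  stop_if_grid_mismatch(cp, cf)
  if (inherits(jac, "sensitivity_map")) {
    w <- sens_weights(jac)
    jac <- sensitivity_states(art_min = w[["artery"]], art_max = w[["artery"]],
                              tis_min = w[["tissue"]], tis_max = w[["tissue"]])
  }
  stopifnot(inherits(jac, "sensitivity_states"))
  t_s <- if (cp$unit == "s") ts_time(cp) else ts_time(cp) * 60
  f_heart <- cfg$heart_rate / 60
  u <- 0.5 + 0.5 * sin(2 * pi * f_heart * t_s + phase)   # 0 = min volume
  jart <- jac$art_min + u * (jac$art_max - jac$art_min)
  jtis <- jac$tis_min + u * (jac$tis_max - jac$tis_min)
  gain <- Iex * optics$eta * optics$epsilon
  out <- cp
  out$values <- gain * (jart * cp$values + jtis * cf$values)
  out$label <- optics$channel
  out
}

#' Remove the DC offset and out-of-band components of a signal
#'
#' FFT-domain filter: the DC bin is zeroed and all components above
#' `cutoff_hz` are removed, leaving the cardiac band untouched (a pure
#' passband tone is returned exactly, minus its mean). With 20 Hz sampling
#' the default 10 Hz cutoff is the Nyquist bin, so the operation reduces to
#' mean removal.
#'
#' @param s A [pdd_ts] sampled in seconds.
#' @param cutoff_hz Keep-band upper edge (Hz), default 10; must not exceed
#'   the Nyquist frequency.
#' @return A zero-mean [pdd_ts] on the same grid.
#' @export
remove_dc <- function(s, cutoff_hz = 10) {
  stopifnot(inherits(s, "pdd_ts"))
  dt_s <- if (s$unit == "s") s$dt else s$dt * 60
  fs <- 1 / dt_s
  if (cutoff_hz > fs / 2 + 1e-12)
    stop("'cutoff_hz' exceeds the Nyquist frequency ", fs / 2, " Hz")
  n <- length(s$values)
  sp <- stats::fft(s$values)
  freq <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  sp[abs(freq) > cutoff_hz | freq == 0] <- 0
  out <- s
  out$values <- Re(stats::fft(sp, inverse = TRUE)) / n
  out
}

#' Apply detector noise and quantization
#'
#' Converts a noise-free signal to detector counts: (1) the signal is
#' scaled so that `scale_ref` (by default its own maximum) maps to the
#' half-maximum count `2^(bit_depth - 1)`; (2) shot noise is sampled from a
#' Poisson distribution with the scaled signal as mean; (3) additive
#' Gaussian noise with SD `gauss_sigma_rel * sd(scaled signal)` models
#' pooled physiological noise; (4) counts are rounded to integers
#' (quantization) and clipped at zero.
#'
#' @param s A [pdd_ts] with non-negative values.
#' @param nm A [noise_model].
#' @param scale_ref Signal level mapped to the half-maximum count; defaults
#'   to `max(s)`. For tumor-channel curves the plasma peak of the agent is
#'   the natural gain reference (see [run_bp_comparison()]).
#' @return A [pdd_ts] of integer counts, with attribute `count_scale`
#'   (counts per signal unit).
#' @export
add_noise <- function(s, nm, scale_ref = NULL) {
  stopifnot(inherits(s, "pdd_ts"), inherits(nm, "noise_model"))
  if (any(s$values < 0)) stop("expected counts must be non-negative")
  if (is.null(scale_ref)) scale_ref <- max(s$values)
  if (scale_ref <= 0) stop("'scale_ref' must be positive")
  if (!is.null(nm$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(nm$seed)
  }
  k <- 2^(nm$bit_depth - 1) / scale_ref
  mu <- s$values * k
  counts <- stats::rpois(length(mu), mu)
  if (nm$gauss_sigma_rel > 0)
    counts <- counts + stats::rnorm(length(mu), 0, nm$gauss_sigma_rel * stats::sd(mu))
  out <- s
  out$values <- pmax(round(counts), 0)
  attr(out, "count_scale") <- k
  out
}

#' Calibrate the Gaussian noise level from a plethysmography trace
#'
#' Fits a 4th-degree polynomial to a one-minute segment of a measured
#' plethysmography signal; the standard deviation of the residuals,
#' relative to the SD of the segment, is taken as the representative
#' relative Gaussian noise level for [noise_model()]. Note that the slow
#' polynomial cannot absorb the cardiac ripple, so the returned value
#' deliberately counts physiological pulsation as "variation".
#'
#' @param pleth A [pdd_ts] of at least one minute, uniformly sampled.
#' @param start Segment start time (same unit as `pleth`), default the
#'   trace start.
#' @return Scalar relative sigma (unitless, >= 0).
#' @export
calibrate_pleth_sigma <- function(pleth, start = NULL) {
  stopifnot(inherits(pleth, "pdd_ts"))
  seg_len <- if (pleth$unit == "s") 60 else 1          # one minute
  tt <- ts_time(pleth)
  if (is.null(start)) start <- tt[1]
  keep <- tt >= start & tt <= start + seg_len
  if (diff(range(tt[keep])) < seg_len - pleth$dt - 1e-9)
    stop("plethysmography segment shorter than one minute")
  y <- pleth$values[keep]
  x <- tt[keep]
  fit <- stats::lm(y ~ stats::poly(x, 4))
  s_y <- stats::sd(y)
  if (s_y == 0) return(0)
  stats::sd(stats::residuals(fit)) / s_y
}
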