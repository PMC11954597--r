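#' Estimate the input-function correction kernel g(t)
#'
#' The targeted and control agents have different plasma input functions;
#' the difference is captured by a kernel `g(t)` such that
#' `Cp_targeted(t) = Cp_control(t) * g(t)` (`*` = convolution). `g` is
#' estimated by truncated-SVD deconvolution: the causal (lower-triangular
#' Toeplitz) discrete convolution matrix `A` of the control curve, scaled
#' by `dt`, is pseudo-inverted with singular values below
#' `trunc * max(singular value)` discarded, and applied to the targeted
#' curve. Both inputs are max-normalized first (reconstructed plasma curves
#' are relative; absolute scale differences are absorbed into `g` and
#' subsequently into the flow-ratio parameter of the reference tissue
#' model).
#'
#' @param cp_tar,cp_con Targeted / control plasma curves: numeric vectors,
#'   [pdd_ts] or [reconstructed_pif] objects on a common uniform grid.
#' @param dt Grid step in minutes (default 1; taken from the inputs when
#'   they carry one).
#' @param trunc Truncation fraction in `[0, 1)`: default 0.02 for noisy
#'   reconstructed inputs; use 0 for noise-free curves.
#' @param normalize Max-normalize the inputs first (default TRUE).
#' @return An object of class `g_function`: list with `values` (kernel on
#'   the `dt` grid), `dt`, `trunc` and `resid_rel` (relative reconvolution
#'   residual `||cp_con * g - cp_tar|| / ||cp_tar||`).
#' @export
estimate_g <- function(cp_tar, cp_con, dt = NULL, trunc = 0.02,
                       normalize = TRUE) {
  get_vals <- function(x) {
    if (inherits(x, "reconstructed_pif")) list(v = x$values, dt = diff(x$time[1:2]))
    else if (inherits(x, "pdd_ts")) list(v = x$values,
                                         dt = if (x$unit == "s") x$dt / 60 else x$dt)
    else list(v = as.numeric(x), dt = NULL)
  }
  a <- get_vals(cp_tar); b <- get_vals(cp_con)
  if (length(a$v) != length(b$v)) stop("input curves must have equal length")
  if (is.null(dt)) dt <- if (!is.null(a$dt)) a$dt else 1
  if (!is.null(a$dt) && !is.null(b$dt) && !isTRUE(all.equal(a$dt, b$dt)))
    stop("input curves are on different grids")
  if (trunc < 0 || trunc >= 1) stop("'trunc' must be in [0, 1)")
  if (all(b$v == 0)) stop("control curve is identically zero: singular system")
  y <- a$v; x <- b$v
  if (normalize) { y <- y / max(y); x <- x / max(x) }
  n <- length(x)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- x[seq_len(n - j + 1)]
  A <- A * dt
  sv <- svd(A)
  keep <- sv$d > trunc * sv$d[1]
  if (!any(keep)) stop("all singular values truncated")
  dinv <- ifelse(keep, 1 / sv$d, 0)
  gvals <- sv$v %*% (dinv * crossprod(sv$u, y))
  gvals <- as.numeric(gvals)
  resid <- sqrt(sum((as.numeric(A %*% gvals) - y)^2)) / sqrt(sum(y^2))
  structure(list(values = gvals, dt = dt, trunc = trunc, resid_rel = resid),
            class = "g_function")
}

#' @export
print.g_function <- function(x, ...) {
  cat(sprintf("<g_function> %d taps at dt = %g min, trunc = %g, reconvolution residual %.3g\n",
              length(x$values), x$dt, x$trunc, x$resid_rel))
  invisible(x)
}

#' Identity correction kernel
#'
#' The discrete unit impulse (`1/dt` at lag zero), i.e. no input-function
#' correction.
#'
#' @param dt Grid step (min).
#' @param n Number of kernel taps (default 1; trailing zeros are implied).
#' @return A `g_function`.
#' @export
g_identity <- function(dt = 1, n = 1L) {
  structure(list(values = c(1 / dt, rep(0, n - 1L)), dt = dt, trunc = 0,
                 resid_rel = 0),
            class = "g_function")
}

#' Apply a correction kernel to a control-agent curve
#'
#' Causal discrete convolution `(ccon * g) dt` (rectangle rule, matching
#' the convolution matrix used by [estimate_g()], so that
#' `apply_g(x, estimate_g(y, x)) == y` up to the truncation error),
#' truncated to the support of the input.
#'
#' @param ccon A [pdd_ts] (minutes grid) or numeric vector.
#' @param g A `g_function` with matching `dt`.
#' @return Same type as `ccon`, corrected.
#' @export
apply_g <- function(ccon, g) {
  stopifnot(inherits(g, "g_function"))
  if (inherits(ccon, "pdd_ts")) {
    dt_in <- if (ccon$unit == "s") ccon$dt / 60 else ccon$dt
    if (!isTRUE(all.equal(dt_in, g$dt)))
      stop("kernel and curve sampling steps differ")
    out <- ccon
    out$values <- conv_causal(ccon$values, g$values, g$dt, rule = "rectangle")
    out
  } else {
    conv_causal(as.numeric(ccon), g$values, g$dt, rule = "rectangle")
  }
}
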