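#' Optical properties of a tissue type
#'
#' @param mu_a Absorption coefficient (cm^-1, >= 0).
#' @param mu_s Scattering coefficient (cm^-1, >= 0).
#' @param g_anis Scattering anisotropy factor, in (-1, 1). Default 0.9.
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s, g_anis = 0.9) {
  if (!is.finite(mu_a) || mu_a < 0) stop("'mu_a' must be >= 0")
  if (!is.finite(mu_s) || mu_s < 0) stop("'mu_s' must be >= 0")
  if (!is.finite(g_anis) || g_anis <= -1 || g_anis >= 1)
    stop("'g_anis' must be in (-1, 1)")
  structure(list(mu_a = mu_a, mu_s = mu_s, g_anis = g_anis),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mu_a=%g mu_s=%g cm^-1, g=%g\n",
              x$mu_a, x$mu_s, x$g_anis))
  invisible(x)
}

#' 800-nm optical properties of the finger tissues
#'
#' Absorption and scattering coefficients (cm^-1) of the five finger
#' regions at 800 nm, anisotropy 0.9 throughout. Both fluorescence channels
#' use this single property set by default (see the package vignette for
#' the limitation this implies); pass a modified list to [run_mc()] for
#' per-channel overrides.
#'
#' @return Named list of [optical_properties], one per region of
#'   [finger_labels()] except background.
#' @export
finger_optics <- function() {
  list(epidermis = optical_properties(10, 8),
       dermis = optical_properties(0.2, 8),
       muscle = optical_properties(0.3, 35),
       bone = optical_properties(0.2, 100),
       artery = optical_properties(0.3, 225))
}

#' Scale blood optical properties with relative vessel volume
#'
#' During the cardiac cycle the arterial vessels dilate and contract.
#' Rather than re-rasterizing the vessel diameter, the absorption and
#' scattering coefficients of the blood voxels are scaled in proportion to
#' the relative vessel volume (number of absorption/scattering events per
#' unit path scales with the amount of blood traversed); the anisotropy
#' factor is unchanged.
#'
#' @param props An [optical_properties] object.
#' @param relative_volume Vessel volume relative to the mean state (> 0);
#'   for a diameter excursion `d`, `relative_volume = (d / d_mean)^2`.
#' @return An [optical_properties] object with scaled `mu_a`, `mu_s`.
#' @export
pulsation_scale <- function(props, relative_volume) {
  stopifnot(inherits(props, "optical_properties"))
  if (!is.finite(relative_volume) || relative_volume <= 0)
    stop("'relative_volume' must be > 0")
  optical_properties(props$mu_a * relative_volume,
                     props$mu_s * relative_volume,
                     props$g_anis)
}

#' Run the voxel Monte Carlo photon simulation
#'
#' Launches photons from a square LED-like top-hat emitter placed above the
#' finger (centered on the cylinder axis midpoint, emitting downward with a
#' Lambertian 90-degree half-angle profile) and returns the fluence volume
#' (track-length estimator, cm^-2 per launched photon). Boundaries are
#' matched (no Fresnel reflection). Identical seeds give bit-identical
#' results.
#'
#' @param labels Label volume from [build_geometry()].
#' @param props Named list of [optical_properties], one entry per non-zero
#'   label name of [finger_labels()] present in `labels` (e.g.
#'   [finger_optics()]).
#' @param n_photons Number of photons to launch (>= 1). Default 1e6.
#' @param seed Integer RNG seed.
#' @param source Optional list with `center` (cm, length-3), `side` (cm)
#'   and `half_angle` (degrees; 90 = Lambertian hemisphere, 0 =
#'   collimated). Default: 1 mm^2 emitter with 90-degree half-angle
#'   centered above the finger.
#' @return 3-D fluence array with attributes `absorbed` and `escaped`
#'   (weight fractions per launched photon), `n_photons` and `seed`.
#' @export
run_mc <- function(labels, props, n_photons = 1e6, seed = 1L, source = NULL) {
  dims <- dim(labels)
  if (is.null(dims) || length(dims) != 3L) stop("'labels' must be a 3-D array")
  if (n_photons < 1) stop("'n_photons' must be >= 1")
  h <- attr(labels, "voxel")
  if (is.null(h)) stop("'labels' lacks a 'voxel' attribute")
  present <- sort(unique(as.integer(labels)))
  lablegend <- finger_labels()
  nlab <- max(present) + 1L
  mua <- mus <- ganis <- numeric(nlab)
  for (l in setdiff(present, 0L)) {
    nm <- names(lablegend)[match(l, lablegend)]
    if (is.na(nm) || is.null(props[[nm]]))
      stop("no optical properties supplied for label ", l)
    p <- props[[nm]]
    stopifnot(inherits(p, "optical_properties"))
    mua[l + 1L] <- p$mu_a; mus[l + 1L] <- p$mu_s; ganis[l + 1L] <- p$g_anis
  }
  if (is.null(source)) {
    source <- list(center = c(dims[1] * h / 2, dims[2] * h / 2,
                              dims[3] * h - h), side = 0.1)
  }
  if (is.null(source$half_angle)) source$half_angle <- 90
  res <- .mc_run(as.integer(labels), as.integer(dims), h,
                 mua, mus, ganis,
                 as.numeric(source$center), source$side,
                 as.numeric(source$half_angle),
                 as.numeric(n_photons), as.integer(seed))
  phi <- array(res$fluence, dim = dims)
  attr(phi, "voxel") <- h
  attr(phi, "absorbed") <- res$absorbed
  attr(phi, "escaped") <- res$escaped
  attr(phi, "n_photons") <- n_photons
  attr(phi, "seed") <- as.integer(seed)
  phi
}

#' Adjoint sensitivity map (Jacobian) of the source-detector pair
#'
#' Forms the per-voxel detection sensitivity as the pixel-by-pixel product
#' of the excitation fluence and the detection probability (the adjoint
#' method). The detection fluence is obtained from the excitation profile
#' by a 180-degree rotation about the y axis (detector diametrically
#' opposite the source, transmission geometry), or can be supplied
#' explicitly from a second simulation.
#'
#' @param phi_ex Excitation fluence volume from [run_mc()].
#' @param labels Label volume (same shape).
#' @param phi_em Optional detection fluence volume; default is the rotated
#'   excitation profile.
#' @param Iex Excitation source intensity (arbitrary units, default 1).
#' @return An object of class `sensitivity_map`: list with `weights` (3-D
#'   array), logical `artery` / `tissue` masks, and `Iex`.
#' @export
make_jacobian <- function(phi_ex, labels, phi_em = NULL, Iex = 1) {
  if (is.null(phi_em)) phi_em <- rotate_y180(phi_ex)
  if (!identical(dim(phi_ex), dim(phi_em)) ||
      !identical(dim(phi_ex), dim(labels)))
    stop("fluence and label volumes must have identical shapes")
  w <- phi_ex * phi_em
  if (any(!is.finite(w))) stop("non-finite Jacobian weights")
  structure(list(weights = w,
                 artery = labels == finger_labels()[["artery"]],
                 tissue = labels > 0L & labels != finger_labels()[["artery"]],
                 Iex = Iex,
                 n_photons = attr(phi_ex, "n_photons")),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  w <- sens_weights(x)
  cat(sprintf("<sensitivity_map> %s voxels; ROI weights: artery %.4g, tissue %.4g\n",
              paste(dim(x$weights), collapse = "x"), w[["artery"]], w[["tissue"]]))
  invisible(x)
}

#' Rotate a volume 180 degrees about the y axis
#'
#' Maps `(x, y, z) -> (-x, y, -z)` about the volume center, i.e. reverses
#' the first and third array indices.
#'
#' @param v 3-D array.
#' @return The rotated array (attributes preserved).
#' @export
rotate_y180 <- function(v) {
  d <- dim(v)
  out <- v[d[1]:1, , d[3]:1, drop = FALSE]
  attributes(out) <- attributes(v)
  out
}

#' ROI-summed sensitivity weights
#'
#' Sums the Jacobian over the arterial and non-arterial (tissue) regions,
#' giving the two scalar weights that multiply the plasma and tissue
#' concentrations in the detected-signal model.
#'
#' @param jac A `sensitivity_map` from [make_jacobian()].
#' @return Named numeric vector `c(artery = , tissue = )`, scaled by `Iex`.
#' @export
sens_weights <- function(jac) {
  stopifnot(inherits(jac, "sensitivity_map"))
  c(artery = jac$Iex * sum(jac$weights[jac$artery]),
    tissue = jac$Iex * sum(jac$weights[jac$tissue]))
}

#' Two-state ROI sensitivity weights for the pulsatile forward model
#'
#' The forward signal model needs the ROI-summed Jacobian weights at the
#' two extremes of the cardiac cycle (minimum and maximum vessel volume);
#' at intermediate phases the weights are interpolated along the same
#' sinusoid as the concentration modulation. This "two-weight" mode lets
#' the full pipeline run without re-simulating photon transport.
#'
#' Only the artery:tissue ratio matters downstream (reconstructed plasma
#' curves are max-normalized), so the tissue weight is normalized to 1.
#' The default artery weight of 1/3 is the vessel volume fraction of a
#' millimeter-scale probe sensing volume containing the two 0.8-mm
#' vessels (vessels dominate a probe column a few millimeters across; see
#' the package vignette). By default the weights carry no cardiac
#' modulation of their own (`min = max`): the arterial volume pulsation
#' enters through the concentration modulation ([modulate_pif()]), and the
#' counteracting optical-attenuation modulation of the weights is below
#' the Monte Carlo resolution at desk-scale photon counts. Supply
#' MC-derived state pairs via [mc_sensitivity_states()] to override.
#'
#' @param art_min,art_max Arterial ROI weight at minimum / maximum vessel
#'   volume.
#' @param tis_min,tis_max Tissue ROI weight at minimum / maximum vessel
#'   volume.
#' @return An object of class `sensitivity_states`.
#' @export
sensitivity_states <- function(art_min = 1 / 3, art_max = 1 / 3,
                               tis_min = 1, tis_max = 1) {
  vals <- c(art_min, art_max, tis_min, tis_max)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("sensitivity weights must be non-negative and finite")
  structure(list(art_min = art_min, art_max = art_max,
                 tis_min = tis_min, tis_max = tis_max),
            class = "sensitivity_states")
}

#' @export
print.sensitivity_states <- function(x, ...) {
  cat(sprintf("<sensitivity_states> artery [%.4g, %.4g], tissue [%.4g, %.4g]\n",
              x$art_min, x$art_max, x$tis_min, x$tis_max))
  invisible(x)
}

#' Derive two-state sensitivity weights from Monte Carlo runs
#'
#' Convenience wrapper: runs the Monte Carlo at minimum and maximum vessel
#' volume (blood optical properties scaled by relative volume) and returns
#' the [sensitivity_states] used by the signal forward model.
#'
#' @param spec A [finger_geometry].
#' @param props Optical property list (default [finger_optics()]).
#' @param n_photons Photons per state.
#' @param seed Integer seed (the two states use `seed` and `seed + 1`).
#' @return A [sensitivity_states] object.
#' @export
mc_sensitivity_states <- function(spec = finger_geometry(),
                                  props = finger_optics(),
                                  n_photons = 1e6, seed = 1L) {
  labels <- build_geometry(spec)
  rel <- c(min = (spec$vessel_diameter_min / spec$vessel_diameter_mean)^2,
           max = (spec$vessel_diameter_max / spec$vessel_diameter_mean)^2)
  w <- lapply(seq_along(rel), function(i) {
    p <- props
    p$artery <- pulsation_scale(p$artery, rel[i])
    phi <- run_mc(labels, p, n_photons = n_photons, seed = seed + i - 1L)
    sens_weights(make_jacobian(phi, labels))
  })
  sensitivity_states(art_min = w[[1]][["artery"]], art_max = w[[2]][["artery"]],
                     tis_min = w[[1]][["tissue"]], tis_max = w[[2]][["tissue"]])
}
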