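#' Layered finger geometry specification
#'
#' Describes the voxelized finger phantom: a cylinder of `length` cm (axis
#' along x) and `diameter` cm (cross-section in the y-z plane) made of four
#' concentric layers (epidermis, dermis, muscle, bone core) plus a number of
#' arterial vessels running parallel to the axis at the dermis/muscle
#' interface, placed symmetrically about the mid-sagittal (x-z) plane.
#'
#' The layer thicknesses plus the bone radius must tile the cylinder radius
#' exactly. The vessel diameter oscillates between `vessel_diameter_min` and
#' `vessel_diameter_max` over the cardiac cycle; the geometry is built at
#' the mean diameter and pulsation is modelled by scaling the blood optical
#' properties with relative vessel volume (see [pulsation_scale()]).
#'
#' @param length Cylinder length (cm).
#' @param diameter Cylinder diameter (cm).
#' @param epidermis,dermis,muscle Layer thicknesses (cm), outermost first.
#' @param bone Bone core diameter (cm).
#' @param vessel_count Number of arterial vessels (default 2).
#' @param vessel_diameter_mean,vessel_diameter_min,vessel_diameter_max
#'   Vessel diameters (cm); `min < mean < max`.
#' @param vessel_angle Angular position of the vessels from the +z (source)
#'   direction, degrees; vessels sit at +/- this angle.
#' @param grid Integer vector of voxels per axis `c(nx, ny, nz)`.
#' @param voxel Isotropic voxel size (cm).
#' @return An object of class `finger_geometry`.
#' @export
finger_geometry <- function(length = 1, diameter = 2,
                            epidermis = 0.15, dermis = 0.15, muscle = 0.2,
                            bone = 1,
                            vessel_count = 2,
                            vessel_diameter_mean = 0.08,
                            vessel_diameter_min = 0.0786,
                            vessel_diameter_max = 0.0832,
                            vessel_angle = 30,
                            grid = c(50L, 100L, 100L),
                            voxel = 0.02) {
  if (voxel <= 0) stop("'voxel' must be > 0")
  R <- diameter / 2
  if (epidermis < 0 || dermis < 0 || muscle < 0 || bone < 0)
    stop("layer thicknesses must be non-negative")
  if (abs(epidermis + dermis + muscle + bone / 2 - R) > 1e-9)
    stop("layer thicknesses plus bone radius must tile the cylinder radius")
  if (!(vessel_diameter_min < vessel_diameter_mean &&
        vessel_diameter_mean < vessel_diameter_max))
    stop("need vessel_diameter_min < mean < max")
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 4L)) stop("'grid' must be 3 positive sizes")
  structure(list(length = length, diameter = diameter,
                 epidermis = epidermis, dermis = dermis, muscle = muscle,
                 bone = bone, vessel_count = as.integer(vessel_count),
                 vessel_diameter_mean = vessel_diameter_mean,
                 vessel_diameter_min = vessel_diameter_min,
                 vessel_diameter_max = vessel_diameter_max,
                 vessel_angle = vessel_angle,
                 grid = grid, voxel = voxel),
            class = "finger_geometry")
}

#' @export
print.finger_geometry <- function(x, ...) {
  cat(sprintf("<finger_geometry> %g x %g cm cylinder, %d voxels of %g cm, %d vessel(s)\n",
              x$length, x$diameter, prod(x$grid), x$voxel, x$vessel_count))
  invisible(x)
}

#' Region labels used by the finger phantom
#'
#' @return Named integer vector mapping region names to voxel labels
#'   (0 is background, outside the finger).
#' @export
finger_labels <- function() {
  c(background = 0L, epidermis = 1L, dermis = 2L, muscle = 3L,
    bone = 4L, artery = 5L)
}

#' Build the voxel label volume of the finger phantom
#'
#' Rasterizes a [finger_geometry] onto its voxel grid. Every voxel whose
#' center lies inside the cylinder receives exactly one region label
#' (epidermis, dermis, muscle, bone or artery); voxels outside are
#' background. Vessels are carved out of the layer volume at the
#' dermis/muscle interface, at their mean diameter.
#'
#' @param spec A [finger_geometry].
#' @return 3-D integer array of labels (see [finger_labels()]), with
#'   attributes `voxel` (cm) and `geometry` (the spec).
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "finger_geometry"))
  n <- spec$grid; h <- spec$voxel
  R <- spec$diameter / 2
  # voxel centers; y and z centered on the cylinder axis
  xs <- (seq_len(n[1]) - 0.5) * h
  ys <- (seq_len(n[2]) - 0.5) * h - n[2] * h / 2
  zs <- (seq_len(n[3]) - 0.5) * h - n[3] * h / 2
  lab <- array(0L, dim = n)
  r2 <- outer(ys^2, zs^2, "+")          # ny x nz squared radius
  r <- sqrt(r2)
  sect <- array(0L, dim = c(n[2], n[3]))
  r_derm <- R - spec$epidermis
  r_musc <- r_derm - spec$dermis
  r_bone <- r_musc - spec$muscle
  sect[r <= R] <- finger_labels()[["epidermis"]]
  sect[r <= r_derm] <- finger_labels()[["dermis"]]
  sect[r <= r_musc] <- finger_labels()[["muscle"]]
  sect[r <= r_bone] <- finger_labels()[["bone"]]
  if (spec$vessel_count > 0) {
    rv <- r_musc                         # dermis/muscle interface
    ang <- spec$vessel_angle * pi / 180
    k <- seq_len(spec$vessel_count)
    signs <- rep(c(1, -1), length.out = spec$vessel_count)
    for (i in k) {
      cy <- rv * sin(signs[i] * ang)
      cz <- rv * cos(ang)
      d2 <- outer((ys - cy)^2, (zs - cz)^2, "+")
      sect[d2 <= (spec$vessel_diameter_mean / 2)^2 & r <= R] <-
        finger_labels()[["artery"]]
    }
  }
  inside_x <- xs <= spec$length
  for (i in which(inside_x)) lab[i, , ] <- sect
  attr(lab, "voxel") <- h
  attr(lab, "geometry") <- spec
  lab
}
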