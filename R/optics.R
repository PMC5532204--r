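#' Optical system configuration
#'
#' Bundles the parameters of the tomographic microscope that the forward and
#' inverse models need: illumination wavelength, condenser and objective
#' numerical apertures, the refractive index of the immersion/imaging medium,
#' and the maximum illumination tilt used by the angular scan.
#'
#' @param wavelength Illumination wavelength in micrometres (default 0.532,
#'   i.e. a 532 nm laser).
#' @param na_condenser Numerical aperture of the condenser (default 1.2).
#' @param na_objective Numerical aperture of the objective (default 1.4).
#' @param n_medium Refractive index of the surrounding medium (default 1.337,
#'   a typical imaging buffer; configurable because instruments differ).
#' @param max_illumination_angle Maximum illumination tilt in degrees
#'   (default 60).
#'
#' @return An object of class `odt_optics`.
#' @export
optics_config <- function(wavelength = 0.532,
                          na_condenser = 1.2,
                          na_objective = 1.4,
                          n_medium = 1.337,
                          max_illumination_angle = 60) {
  stopifnot(wavelength > 0, na_condenser > 0, na_objective > 0)
  if (!(n_medium > 1.0 && n_medium < 1.40))
    stop_labeled("optics", "n_medium must lie in (1.0, 1.40), got ", n_medium)
  if (!(max_illumination_angle > 0 && max_illumination_angle <= 90))
    stop_labeled("optics", "max_illumination_angle must be in (0, 90] degrees")
  structure(
    list(wavelength = wavelength,
         na_condenser = na_condenser,
         na_objective = na_objective,
         n_medium = n_medium,
         max_illumination_angle = max_illumination_angle),
    class = "odt_optics")
}

#' Reconstruction/rendering grid specification
#'
#' @param shape Integer vector of three voxel counts (default `c(96, 96, 96)`).
#' @param voxel_pitch Voxel pitch in micrometres per axis; a scalar is
#'   recycled to all three axes (default 0.1 um isotropic).
#'
#' @return An object of class `odt_grid` with fields `shape`, `voxel_pitch`
#'   and the derived physical `extent` (um).
#' @export
grid_spec <- function(shape = c(96L, 96L, 96L), voxel_pitch = 0.1) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  stopifnot(length(shape) == 3L)
  if (any(shape < 16L))
    stop_labeled("grid", "all voxel counts must be >= 16")
  voxel_pitch <- as.numeric(voxel_pitch)
  if (length(voxel_pitch) == 1L) voxel_pitch <- rep(voxel_pitch, 3L)
  stopifnot(length(voxel_pitch) == 3L, all(voxel_pitch > 0))
  structure(
    list(shape = shape, voxel_pitch = voxel_pitch,
         extent = shape * voxel_pitch),
    class = "odt_grid")
}

#' @export
print.odt_grid <- function(x, ...) {
  cat(sprintf("<odt_grid> %d x %d x %d voxels, pitch %.3g/%.3g/%.3g um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3]))
  invisible(x)
}

#' @export
print.odt_optics <- function(x, ...) {
  cat(sprintf(
    "<odt_optics> lambda %.3g um, NA cond/obj %.2f/%.2f, n_medium %.4f\n",
    x$wavelength, x$na_condenser, x$na_objective, x$n_medium))
  invisible(x)
}

# angular frequency grids (rad/um) in FFT index order
k_freq <- function(n, pitch) {
  2 * pi * c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * pitch)
}

# voxel-centre physical coordinates of a grid axis, origin at first voxel
axis_coords <- function(n, pitch) (seq_len(n) - 1) * pitch
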