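#' Circular set of illumination directions
#'
#' Unit direction vectors on a cone of half-angle `tilt_deg` about the
#' optical (z) axis, evenly spaced in azimuth — the usual circular angular
#' scan of a tomographic microscope.
#'
#' @param n Number of directions (default 40).
#' @param tilt_deg Polar tilt in degrees (default 55).
#' @param optics [optics_config()]; used to check the condenser NA.
#' @return `n x 3` matrix of unit vectors.
#' @export
illumination_directions <- function(n = 40, tilt_deg = 55,
                                    optics = optics_config()) {
  th <- tilt_deg * pi / 180
  if (optics$n_medium * sin(th) > optics$na_condenser + 1e-9)
    stop_labeled("directions", "tilt exceeds the condenser NA cone")
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th), n))
}

# Ewald-cap frequency bookkeeping shared by the forward model and the
# spectrum mapper. For one illumination direction, returns for every
# admissible detector frequency: its (i,j) index in the 2-D FFT grid, the
# axial wavenumber kz, and the 1-based (x,y,z) indices of the nearest voxel
# of the 3-D frequency grid at K = k_scattered - k_incident.
ewald_cap <- function(direction, optics, grid) {
  k0 <- 2 * pi / optics$wavelength
  km <- k0 * optics$n_medium
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  kx <- k_freq(nx, grid$voxel_pitch[1])
  ky <- k_freq(ny, grid$voxel_pitch[2])
  KX <- matrix(kx, nx, ny)
  KY <- matrix(ky, nx, ny, byrow = TRUE)
  kr2 <- KX^2 + KY^2
  ok <- kr2 <= (k0 * optics$na_objective)^2 & kr2 < km^2 * (1 - 1e-9)
  kin <- km * direction
  kz <- sqrt(pmax(km^2 - kr2, 0))
  Kx <- KX - kin[1]; Ky <- KY - kin[2]; Kz <- kz - kin[3]
  # nearest voxel of the 3-D frequency grid
  ix <- round(Kx * nx * grid$voxel_pitch[1] / (2 * pi))
  iy <- round(Ky * ny * grid$voxel_pitch[2] / (2 * pi))
  iz <- round(Kz * nz * grid$voxel_pitch[3] / (2 * pi))
  inband <- abs(ix) <= nx / 2 - 1 & abs(iy) <= ny / 2 - 1 &
    abs(iz) <= nz / 2 - 1
  use <- ok & inband
  if (sum(use) < 0.5 * sum(ok))
    stop_labeled("map_spectrum",
                 "grid too coarse for the maximum transferred frequency")
  to1 <- function(i, n) ifelse(i >= 0, i + 1, n + i + 1)
  list(sel = which(use),
       kz = kz[use],
       vox = cbind(to1(ix[use], nx), to1(iy[use], ny), to1(iz[use], nz)))
}

#' Simulate the complex fields an ODT instrument would measure
#'
#' First-order (Rytov) forward model: the 3-D spectrum of the scattering
#' potential `f = k0^2 (n^2 - n_medium^2)` is sampled on the Ewald cap of
#' each illumination direction (Fourier diffraction theorem), giving the 2-D
#' spectrum of the complex Rytov phase; the returned per-angle field is
#' `exp(psi)`, normalised to unit incident field. A homogeneous volume
#' yields unit-amplitude zero-phase fields.
#'
#' @param tomo `odt_tomogram`.
#' @param directions `n x 3` matrix of unit illumination directions, all
#'   within the condenser NA cone.
#' @param optics [optics_config()].
#' @return Object of class `odt_field_stack`: list with `fields` (list of
#'   complex matrices), `directions`, `pixel_pitch`, `optics`.
#' @export
forward_fields <- function(tomo, directions, optics = optics_config()) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop_labeled("forward", "directions must be unit vectors")
  sperp <- sqrt(directions[, 1]^2 + directions[, 2]^2)
  if (any(optics$n_medium * sperp > optics$na_condenser + 1e-9))
    stop_labeled("forward", "direction outside the condenser NA cone")
  dn_max <- max(tomo$values) - tomo$n_medium
  if (dn_max > 0.1)
    warning("max RI contrast ", signif(dn_max, 3),
            " exceeds the weak-scattering regime (0.1)")

  grid <- tomo$grid
  k0 <- 2 * pi / optics$wavelength
  f <- k0^2 * (tomo$values^2 - optics$n_medium^2)
  Fc <- fft(f) * prod(grid$voxel_pitch)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  norm2d <- nx * grid$voxel_pitch[1] * ny * grid$voxel_pitch[2]

  fields <- lapply(seq_len(nrow(directions)), function(i) {
    cap <- ewald_cap(directions[i, ], optics, grid)
    Psi <- matrix(0 + 0i, nx, ny)
    Psi[cap$sel] <- (1i / (2 * cap$kz)) * Fc[cap$vox]
    psi <- fft(Psi, inverse = TRUE) / norm2d
    exp(psi)
  })
  structure(list(fields = fields, directions = directions,
                 pixel_pitch = grid$voxel_pitch[1:2], optics = optics),
            class = "odt_field_stack")
}

#' Synthesize an off-axis hologram from a complex field
#'
#' Interferes the sample field with a tilted plane-wave reference:
#' `H = |E_s + exp(2*pi*i*(f_c . r))|^2`. The carrier frequency is snapped
#' to the discrete frequency grid (and recorded in the hologram metadata)
#' so that demodulation is exact.
#'
#' The carrier is expressed in sample-plane coordinates. In an off-axis
#' interferometer the reference tilt lives at the camera, where the
#' microscope magnification has stretched the field; mapped back to the
#' sample plane the effective carrier can therefore exceed `1/wavelength`.
#' The default, 0.35 of the sampling frequency per axis, leaves the
#' sideband well separated from the autocorrelation term while keeping the
#' crop radius larger than the NA-limited field bandwidth. Alternatively a
#' physical `reference_tilt` (degrees, tilt in air) can be given.
#'
#' @param field Complex matrix (sample field, unit-normalised).
#' @param carrier Carrier frequency in cycles/um, length-2; default 0.35 of
#'   the camera sampling frequency per axis. Ignored when `reference_tilt`
#'   is given.
#' @param reference_tilt Optional reference-beam tilt in degrees (length 2);
#'   implies `carrier = sin(tilt) / wavelength`.
#' @param optics [optics_config()].
#' @param pixel_pitch Field pixel pitch in um (length 1 or 2).
#' @param illumination_direction Optional unit 3-vector stored as metadata.
#' @param oversample Integer camera oversampling factor (default 4): the
#'   interference pattern is sampled on a grid this much finer than the
#'   field (Fourier zero-padding interpolation), mimicking the fine camera
#'   sampling that off-axis holography needs to keep the modulated sideband
#'   alias-free. [retrieve_field()] returns the field on the original grid.
#' @return Object of class `odt_hologram`.
#' @export
synthesize_hologram <- function(field, carrier = NULL,
                                reference_tilt = NULL,
                                optics = optics_config(),
                                pixel_pitch = 0.1,
                                illumination_direction = c(0, 0, 1),
                                oversample = 4L) {
  if (length(pixel_pitch) == 1L) pixel_pitch <- rep(pixel_pitch, 2L)
  oversample <- as.integer(oversample)
  stopifnot(oversample >= 1L)
  nx <- nrow(field); ny <- ncol(field)
  nfx <- nx * oversample; nfy <- ny * oversample
  fine_pitch <- pixel_pitch / oversample
  fc <- if (!is.null(reference_tilt)) {
    sin(reference_tilt * pi / 180) / optics$wavelength
  } else {
    carrier %||% (0.35 / fine_pitch)
  }
  nyq <- 1 / (2 * fine_pitch)
  if (any(abs(fc) >= nyq))
    stop_labeled("hologram", "carrier frequency at or above Nyquist")
  # snap the carrier to the discrete frequency grid of the camera
  ic <- round(fc * c(nfx, nfy) * fine_pitch)
  fc <- ic / (c(nfx, nfy) * fine_pitch)
  # band-limited interpolation of the field onto the camera grid
  u_fine <- if (oversample == 1L) field else {
    U <- fft(field)
    Up <- matrix(0 + 0i, nfx, nfy)
    hx <- nx %/% 2; hy <- ny %/% 2
    sx <- c(1:hx, (nfx - hx + 1):nfx)
    sy <- c(1:hy, (nfy - hy + 1):nfy)
    Up[sx, sy] <- U[c(1:hx, (nx - hx + 1):nx), c(1:hy, (ny - hy + 1):ny)]
    fft(Up, inverse = TRUE) / (nx * ny)
  }
  x <- axis_coords(nfx, fine_pitch[1])
  y <- axis_coords(nfy, fine_pitch[2])
  phase <- outer(2 * pi * fc[1] * x, 2 * pi * fc[2] * y, "+")
  H <- Mod(u_fine + exp(1i * phase))^2
  structure(list(values = H, pixel_pitch = fine_pitch,
                 carrier_frequency = fc,
                 oversample = oversample,
                 field_shape = c(nx, ny),
                 illumination_direction = illumination_direction),
            class = "odt_hologram")
}

#' Measure a full hologram stack of a phantom
#'
#' Convenience wrapper: forward fields for all directions, plus an empty
#' (background) hologram, everything with a common carrier.
#'
#' @inheritParams forward_fields
#' @param carrier Carrier frequency in cycles/um (see
#'   [synthesize_hologram()]).
#' @return List with `holograms` (list of `odt_hologram`) and `background`.
#' @export
simulate_hologram_stack <- function(tomo, directions,
                                    optics = optics_config(),
                                    carrier = NULL) {
  stack <- forward_fields(tomo, directions, optics)
  holos <- lapply(seq_along(stack$fields), function(i)
    synthesize_hologram(stack$fields[[i]], carrier = carrier,
                        optics = optics, pixel_pitch = stack$pixel_pitch,
                        illumination_direction = directions[i, ]))
  bg_field <- matrix(1 + 0i, nrow(stack$fields[[1]]),
                     ncol(stack$fields[[1]]))
  bg <- synthesize_hologram(bg_field, carrier = carrier, optics = optics,
                            pixel_pitch = stack$pixel_pitch)
  list(holograms = holos, background = bg)
}
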