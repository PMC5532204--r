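#' Reconstruction settings
#'
#' @param use_rytov Use the Rytov linearization (complex log of the
#'   normalised field); `FALSE` selects the first Born variant (`u - 1`).
#' @param iterations Non-negativity (missing-cone) iterations (default 100).
#' @param relaxation Step size in (0, 1] for the object-space projection.
#' @param ri_floor RI floor for the non-negativity constraint; defaults to
#'   the medium RI (i.e. `delta n >= 0`).
#' @param tol Early-stop tolerance on the relative object update
#'   (default 1e-6).
#' @param hermitian Complete the measured spectrum with its Hermitian
#'   conjugate before inversion (default TRUE). Exact for absorption-free
#'   samples (real scattering potential), where it doubles the effective
#'   Ewald coverage; disable for absorbing samples.
#' @return Object of class `odt_recon_settings`.
#' @export
recon_settings <- function(use_rytov = TRUE, iterations = 100L,
                           relaxation = 1.0, ri_floor = NULL, tol = 1e-6,
                           hermitian = TRUE) {
  stopifnot(iterations >= 0, relaxation > 0, relaxation <= 1)
  structure(list(use_rytov = use_rytov, iterations = as.integer(iterations),
                 relaxation = relaxation, ri_floor = ri_floor, tol = tol,
                 hermitian = isTRUE(hermitian)),
            class = "odt_recon_settings")
}

#' Retrieve the complex field from an off-axis hologram
#'
#' Fourier-transform demodulation: the hologram spectrum sideband carrying
#' the sample field is cropped (circular window of half the carrier
#' frequency), shifted to baseband and inverse-transformed. The result is
#' divided by the field retrieved from the background (empty) hologram,
#' which removes the reference/illumination structure.
#'
#' @param hologram,background `odt_hologram` objects sharing shape, pitch
#'   and carrier.
#' @return Object of class `odt_field`: list with `field` (complex matrix),
#'   `pixel_pitch`, `illumination_direction`.
#' @export
retrieve_field <- function(hologram, background) {
  if (!all(dim(hologram$values) == dim(background$values)))
    stop_labeled("retrieve", "hologram and background shapes differ")
  if (any(abs(hologram$carrier_frequency - background$carrier_frequency) >
          1e-12))
    stop_labeled("retrieve", "hologram and background carriers differ")
  demod <- function(h) {
    v <- h$values
    nfx <- nrow(v); nfy <- ncol(v)
    os <- h$oversample %||% 1L
    ncx <- nfx %/% os; ncy <- nfy %/% os
    ic <- round(h$carrier_frequency * c(nfx, nfy) * h$pixel_pitch)
    r_idx <- 0.5 * sqrt(sum(ic^2))
    if (r_idx < 1 || sqrt(sum(ic^2)) <= r_idx)
      stop_labeled("retrieve", "carrier/bandwidth overlap")
    F <- fft(v)
    # shift so the sideband at -carrier moves to DC
    sh <- function(M, s) {
      s <- s %% dim(M)
      M[(seq_len(nrow(M)) - 1 - s[1]) %% nrow(M) + 1,
        (seq_len(ncol(M)) - 1 - s[2]) %% ncol(M) + 1, drop = FALSE]
    }
    Fs <- sh(F, ic)
    fi <- c(0:(nfx / 2), -((nfx - nfx / 2 - 1):1))[seq_len(nfx)]
    fj <- c(0:(nfy / 2), -((nfy - nfy / 2 - 1):1))[seq_len(nfy)]
    d2 <- outer(fi^2, fj^2, "+")
    Fs[d2 > r_idx^2] <- 0 + 0i
    # fold back to the field grid: take the coarse-band spectrum block
    if (os > 1L) {
      hx <- ncx %/% 2; hy <- ncy %/% 2
      Uc <- matrix(0 + 0i, ncx, ncy)
      sxc <- c(1:hx, (ncx - hx + 1):ncx)
      syc <- c(1:hy, (ncy - hy + 1):ncy)
      Uc[sxc, syc] <- Fs[c(1:hx, (nfx - hx + 1):nfx),
                         c(1:hy, (nfy - hy + 1):nfy)]
      Fs <- Uc
    }
    fft(Fs, inverse = TRUE) / (nfx * nfy)
  }
  us <- demod(hologram)
  ub <- demod(background)
  amp <- Mod(ub)
  ub[amp < 1e-9] <- 1e-9
  os <- hologram$oversample %||% 1L
  structure(list(field = us / ub,
                 pixel_pitch = hologram$pixel_pitch * os,
                 illumination_direction = hologram$illumination_direction),
            class = "odt_field")
}

#' Complex Rytov phase of a retrieved field
#'
#' `log(amplitude) + i * unwrapped phase`, with the amplitude floored at
#' 1e-6 before taking the logarithm and the phase unwrapped by the
#' path-independent least-squares method ([unwrap_phase()]).
#'
#' @param field Complex matrix or `odt_field`.
#' @return Complex matrix of Rytov phases.
#' @export
rytov_field <- function(field) {
  u <- if (inherits(field, "odt_field")) field$field else field
  if (any(!is.finite(Re(u))) || any(!is.finite(Im(u))))
    stop_labeled("rytov", "non-finite field values")
  amp <- pmax(Mod(u), 1e-6)
  log(amp) + 1i * unwrap_phase(Arg(u))
}

#' Map Rytov phase spectra onto the 3-D scattering-potential spectrum
#'
#' Fourier diffraction theorem: the 2-D spectrum of each complex Rytov
#' phase is placed on the Ewald-sphere cap of its illumination direction in
#' the 3-D frequency grid of the scattering potential, using nearest-voxel
#' assignment; overlapping contributions are averaged by multiplicity
#' weights at inversion time.
#'
#' @param psis List of complex Rytov-phase matrices (one per direction).
#' @param directions `n x 3` matrix of unit illumination directions.
#' @param optics [optics_config()].
#' @param grid [grid_spec()] of the target tomogram.
#' @return Object of class `odt_spectrum`: `sum` (complex array), `weight`
#'   (array of counts), `grid`, `optics`.
#' @export
map_spectrum <- function(psis, directions, optics = optics_config(),
                         grid = grid_spec(c(64, 64, 64))) {
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  stopifnot(length(psis) == nrow(directions))
  acc <- array(0 + 0i, grid$shape)
  wgt <- array(0, grid$shape)
  # canonical direction order makes accumulation order-invariant
  ord <- order(directions[, 3], directions[, 2], directions[, 1])
  d2 <- prod(grid$voxel_pitch[1:2])
  for (i in ord) {
    psi <- psis[[i]]
    if (!all(dim(psi) == c(nx, ny)))
      stop_labeled("map_spectrum", "field shape does not match grid")
    cap <- ewald_cap(directions[i, ], optics, grid)
    Psi <- fft(psi) * d2
    contrib <- (2 * cap$kz / 1i) * Psi[cap$sel]
    lin <- (cap$vox[, 1] - 1) + nx * (cap$vox[, 2] - 1) +
      nx * ny * (cap$vox[, 3] - 1) + 1
    agg <- rowsum(cbind(Re(contrib), Im(contrib), 1), group = lin)
    tgt <- as.integer(rownames(agg))
    acc[tgt] <- acc[tgt] + complex(real = agg[, 1], imaginary = agg[, 2])
    wgt[tgt] <- wgt[tgt] + agg[, 3]
  }
  structure(list(sum = acc, weight = wgt, grid = grid, optics = optics),
            class = "odt_spectrum")
}

#' Invert the accumulated spectrum with missing-cone regularization
#'
#' Gerchberg-Papoulis-style alternating projection: inverse-transform the
#' current spectrum, clamp the scattering potential from below (RI floor,
#' i.e. non-negativity of the RI excess over the medium), forward-transform,
#' and re-impose the measured spectrum on its support. With
#' `iterations = 0` this returns the direct (unregularized) inversion.
#'
#' @param acc `odt_spectrum` from [map_spectrum()].
#' @param settings [recon_settings()].
#' @return `odt_tomogram`.
#' @export
regularize_missing_cone <- function(acc, settings = recon_settings()) {
  if (!any(acc$weight > 0))
    stop_labeled("regularize", "accumulator has no measured support")
  optics <- acc$optics
  grid <- acc$grid
  k0 <- 2 * pi / optics$wavelength
  nm <- optics$n_medium
  ri_floor <- settings$ri_floor %||% nm
  f_floor <- k0^2 * (ri_floor^2 - nm^2)
  supp <- acc$weight > 0
  Fmeas <- array(0 + 0i, grid$shape)
  Fmeas[supp] <- acc$sum[supp] / acc$weight[supp]
  if (settings$hermitian) {
    # real scattering potential: F(-K) = conj(F(K)); fill unmeasured
    # conjugate voxels
    rev_idx <- function(n) c(1L, n:2L)
    rx <- rev_idx(grid$shape[1]); ry <- rev_idx(grid$shape[2])
    rz <- rev_idx(grid$shape[3])
    Fc <- Conj(Fmeas[rx, ry, rz])
    sc <- supp[rx, ry, rz]
    fill <- sc & !supp
    Fmeas[fill] <- Fc[fill]
    supp <- supp | sc
  }
  normc <- prod(grid$shape) * prod(grid$voxel_pitch)

  f <- fft(Fmeas, inverse = TRUE) / normc
  e0 <- sum(Mod(f)^2)
  if (settings$iterations > 0) {
    # each cycle ends on the object-space projection, so the returned
    # volume satisfies the RI floor (up to the relaxation step)
    for (it in seq_len(settings$iterations)) {
      f_prev <- f
      fr <- Re(f)
      fr_new <- fr + settings$relaxation * (pmax(fr, f_floor) - fr)
      Fcur <- fft(fr_new + 1i * Im(f)) * prod(grid$voxel_pitch)
      Fcur[supp] <- Fmeas[supp]
      f <- fft(Fcur, inverse = TRUE) / normc
      if (sum(Mod(f)^2) > 10 * max(e0, 1e-300))
        stop_labeled("regularize", "iteration diverged (energy growth > 10x)")
      upd <- sqrt(sum(Mod(f - f_prev)^2) / max(sum(Mod(f_prev)^2), 1e-300))
      if (it == settings$iterations || upd < settings$tol) {
        fr <- Re(f)
        f <- fr + settings$relaxation * (pmax(fr, f_floor) - fr) + 1i * Im(f)
        break
      }
    }
  }
  n_vals <- sqrt(pmax(nm^2 + Re(f) / k0^2, 0))
  tomogram(array(n_vals, grid$shape), grid, nm)
}

#' Reconstruct a tomogram from a stack of off-axis holograms
#'
#' Full inverse pipeline: Fourier-transform field retrieval with background
#' normalisation, Rytov (or Born) linearization, Ewald-cap spectrum mapping,
#' and iterative non-negativity regularization of the missing cone.
#' Deterministic; the result is independent of hologram ordering.
#'
#' @param holograms List of `odt_hologram` with distinct illumination
#'   directions (at least 3).
#' @param background Background (empty-field) `odt_hologram`.
#' @param optics [optics_config()].
#' @param grid [grid_spec()] of the output tomogram.
#' @param settings [recon_settings()].
#' @return `odt_tomogram`; attribute `"recon_info"` records settings and
#'   direction count.
#' @export
reconstruct_tomogram <- function(holograms, background,
                                 optics = optics_config(),
                                 grid = grid_spec(c(64, 64, 64)),
                                 settings = recon_settings()) {
  if (length(holograms) < 3)
    stop_labeled("reconstruct", "need at least 3 holograms")
  directions <- t(vapply(holograms,
                         function(h) h$illumination_direction, numeric(3)))
  if (anyDuplicated(round(directions, 12)) &&
      nrow(unique(round(directions, 12))) < 3)
    stop_labeled("reconstruct", "need >= 3 distinct illumination directions")
  psis <- lapply(holograms, function(h) {
    fld <- retrieve_field(h, background)
    if (settings$use_rytov) rytov_field(fld) else fld$field - 1
  })
  acc <- map_spectrum(psis, directions, optics, grid)
  out <- regularize_missing_cone(acc, settings)
  attr(out, "recon_info") <- list(n_directions = nrow(directions),
                                  settings = settings)
  out
}
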