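#' Per-class phantom parameters
#'
#' Describes the class-conditional distributions from which lymphocyte-like
#' phantoms are drawn: cell volume, target sphericity, cell-mean protein
#' density, and the internal-structure settings (nucleus volume fraction,
#' nucleolus count/size and the density offsets of nucleus and nucleoli over
#' the cytoplasm).
#'
#' The morphological and biochemical means/SDs default, per class, to the
#' published population statistics for murine B, CD4+ T and CD8+ T
#' lymphocytes (see [default_class_params()]). The internal-structure
#' parameters are modelling choices, constrained so that all compartment RI
#' values stay in the 1.34-1.41 range typical of lymphocytes.
#'
#' @param label Class label, one of `"B"`, `"CD4T"`, `"CD8T"`.
#' @param volume_mean,volume_sd Cell volume distribution, fL.
#' @param sphericity_mean,sphericity_sd Target sphericity distribution
#'   (dimensionless, in (0, 1]).
#' @param density_mean,density_sd Cell-mean protein density, g/dL.
#' @param nucleus_volume_fraction Fraction of cell volume occupied by the
#'   nucleus (default 0.6).
#' @param nucleus_density_offset Nucleus protein density minus cytoplasm
#'   density, g/dL (default 2).
#' @param nucleolus_count_range Integer range of nucleolus counts
#'   (default `c(1L, 3L)`).
#' @param nucleolus_radius Nucleolus radius, um (default 0.4).
#' @param nucleolus_density_offset Nucleolus density minus nucleus density,
#'   g/dL (default 6).
#'
#' @return An object of class `odt_class_params`.
#' @export
class_params <- function(label,
                         volume_mean, volume_sd,
                         sphericity_mean, sphericity_sd,
                         density_mean, density_sd,
                         nucleus_volume_fraction = 0.6,
                         nucleus_density_offset = 2,
                         nucleolus_count_range = c(1L, 3L),
                         nucleolus_radius = 0.4,
                         nucleolus_density_offset = 6) {
  stopifnot(volume_sd >= 0, sphericity_sd >= 0, density_sd >= 0,
            nucleolus_radius > 0)
  if (!(nucleus_volume_fraction > 0 && nucleus_volume_fraction < 1))
    stop_labeled("class_params", "nucleus_volume_fraction must be in (0, 1)")
  structure(
    list(label = label,
         volume_mean = volume_mean, volume_sd = volume_sd,
         sphericity_mean = sphericity_mean, sphericity_sd = sphericity_sd,
         density_mean = density_mean, density_sd = density_sd,
         nucleus_volume_fraction = nucleus_volume_fraction,
         nucleus_density_offset = nucleus_density_offset,
         nucleolus_count_range = as.integer(nucleolus_count_range),
         nucleolus_radius = nucleolus_radius,
         nucleolus_density_offset = nucleolus_density_offset),
    class = "odt_class_params")
}

#' Default phantom parameters for the three lymphocyte classes
#'
#' Means and standard deviations of cell volume, sphericity and cell-mean
#' protein density are set to the published single-cell population statistics
#' of sorted murine lymphocytes: B cells 133.43 +/- 26.47 fL, 0.86 +/- 0.06,
#' 15.43 +/- 1.88 g/dL; CD4+ T cells 155.73 +/- 35.14 fL, 0.84 +/- 0.06,
#' 14.81 +/- 2.54 g/dL; CD8+ T cells 152.77 +/- 26.52 fL, 0.86 +/- 0.05,
#' 16.66 +/- 1.88 g/dL. Surface area and dry mass are not sampled directly:
#' they follow from volume, sphericity and density.
#'
#' The internal-structure defaults encode the qualitative picture reported
#' for these cells: B cells show a well-defined nucleus and nucleoli with a
#' comparatively dim cytosol, whereas the T cells have a higher cytosolic RI
#' and flatter internal contrast. With the cell-mean density fixed by the
#' population statistics, this is expressed through the nucleus/cytoplasm
#' density offset: 5 g/dL for B cells, 1.5 g/dL for both T classes. All
#' compartment RI values stay within the 1.34-1.41 range observed for
#' lymphocytes.
#'
#' @return Named list of [class_params()] objects for `B`, `CD4T`, `CD8T`.
#' @export
default_class_params <- function() {
  list(
    B    = class_params("B",    133.43, 26.47, 0.86, 0.06, 15.43, 1.88,
                        nucleus_density_offset = 5),
    CD4T = class_params("CD4T", 155.73, 35.14, 0.84, 0.06, 14.81, 2.54,
                        nucleus_density_offset = 1.5),
    CD8T = class_params("CD8T", 152.77, 26.52, 0.86, 0.05, 16.66, 1.88,
                        nucleus_density_offset = 1.5)
  )
}

# surface area of an oblate spheroid with semi-axes (a, a, q*a), q <= 1
oblate_area <- function(a, q) {
  if (q >= 1 - 1e-9) return(4 * pi * a^2)
  e <- sqrt(1 - q^2)
  2 * pi * a^2 * (1 + (q^2 / e) * atanh(e))
}

# sphericity of an oblate spheroid as a function of the axis ratio q
oblate_sphericity <- function(q) {
  a <- 1
  V <- 4 / 3 * pi * q * a^3
  S <- oblate_area(a, q)
  pi^(1 / 3) * (6 * V)^(2 / 3) / S
}

# invert sphericity -> axis ratio on [q_floor, 1]; if even the flattest
# admissible spheroid is rounder than the target, return the floor.
solve_axis_ratio <- function(target, q_floor = 0.2) {
  target <- min(target, 1)
  if (target >= 1 - 1e-9) return(1)
  if (oblate_sphericity(q_floor) >= target) return(q_floor)
  uniroot(function(q) oblate_sphericity(q) - target,
          lower = q_floor, upper = 1, tol = 1e-10)$root
}

# uniform random rotation matrix (det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

runif_ball <- function(r = 1) {
  v <- rnorm(3)
  v / sqrt(sum(v^2)) * r * runif(1)^(1 / 3)
}

draw_positive <- function(mean, sd, floor = 0, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x > floor) return(x)
  }
  stop_labeled("sample_geometry",
               "could not draw a value > ", floor, " from N(", mean, ", ",
               sd, ") in ", max_tries, " tries")
}

#' Sample a random cell geometry for one phantom
#'
#' Draws cell volume, target sphericity and cell-mean protein density from
#' the class-conditional normal distributions, maps the sphericity target to
#' an oblate-spheroid axis ratio, and places a nucleus (fixed volume
#' fraction, same orientation) and 1-3 nucleolus spheres strictly inside it.
#' Compartment densities are solved so that the volume-weighted mean density
#' of the rendered compartments equals the drawn cell-mean density exactly.
#'
#' The flattening needed to reach a given sphericity is capped so that the
#' cell always fits the target grid with a 0.5 um margin in any orientation;
#' extreme draws therefore come out rounder than their nominal target (see
#' the methods vignette).
#'
#' @param label Class label with an entry in `params`.
#' @param params Named list of [class_params()] (default
#'   [default_class_params()]).
#' @param grid [grid_spec()] the phantom must fit into (default 96^3 at
#'   0.1 um); only its physical extent is used here.
#' @param seed Integer seed; the drawn geometry is a pure function of
#'   (`label`, `params`, `grid`, `seed`).
#'
#' @return An object of class `odt_geometry`.
#' @export
sample_geometry <- function(label, params = default_class_params(),
                            grid = grid_spec(), seed = NULL) {
  if (inherits(params, "odt_class_params")) {
    cp <- params
  } else {
    if (!label %in% names(params))
      stop_labeled("sample_geometry", "unknown label '", label, "'")
    cp <- params[[label]]
  }
  draw <- function() {
    volume <- draw_positive(cp$volume_mean, cp$volume_sd, floor = 1)
    sph <- min(draw_positive(cp$sphericity_mean, cp$sphericity_sd,
                             floor = 0.3), 0.999)
    dbar <- draw_positive(cp$density_mean, cp$density_sd, floor = 5)

    margin <- 0.5
    a_max <- min(grid$extent) / 2 - margin
    # axis ratio: sphericity target, subject to the grid-fit cap on the
    # equatorial semi-axis (rotation-proof: bounding radius is max semiaxis)
    q_geom_floor <- max(0.2, 3 * volume / (4 * pi * a_max^3))
    if (q_geom_floor >= 1) {
      q <- 1
      a <- (3 * volume / (4 * pi))^(1 / 3)
      if (a > a_max)
        stop_labeled("sample_geometry",
                     "drawn volume ", round(volume, 1),
                     " fL cannot fit the grid extent")
    } else {
      q <- solve_axis_ratio(sph, q_floor = q_geom_floor)
      a <- (3 * volume / (4 * pi * q))^(1 / 3)
    }
    semiaxes <- c(a, a, q * a)
    rot <- random_rotation()
    center <- grid$extent / 2

    f <- cp$nucleus_volume_fraction
    rho <- f^(1 / 3)
    nuc_semiaxes <- semiaxes * rho
    # in cell-normalised coordinates the nucleus is a ball of radius rho;
    # keep it strictly inside with a 40% slack on the admissible offset
    off_norm <- runif_ball(1) * (1 - rho) * 0.6
    nuc_center_local <- off_norm * semiaxes
    nuc_center <- center + as.vector(rot %*% nuc_center_local)

    # nucleoli: disjoint spheres strictly inside the nucleus
    n_nlo <- if (cp$nucleolus_count_range[1] == cp$nucleolus_count_range[2])
      cp$nucleolus_count_range[1]
    else sample(cp$nucleolus_count_range[1]:cp$nucleolus_count_range[2], 1)
    r_nlo <- cp$nucleolus_radius
    if (r_nlo >= 0.9 * min(nuc_semiaxes)) n_nlo <- 0L
    nucleoli <- list()
    if (n_nlo > 0) {
      rho_max <- r_nlo / min(nuc_semiaxes)
      for (i in seq_len(n_nlo)) {
        placed <- FALSE
        for (try in 1:100) {
          u <- runif_ball(1) * (1 - rho_max)
          cand <- nuc_center + as.vector(rot %*% (u * nuc_semiaxes))
          ok <- TRUE
          for (nl in nucleoli)
            if (sqrt(sum((cand - nl$center)^2)) <= 2 * r_nlo) { ok <- FALSE; break }
          if (ok) {
            nucleoli[[length(nucleoli) + 1L]] <-
              list(center = cand, radius = r_nlo)
            placed <- TRUE
            break
          }
        }
        if (!placed) break  # accept fewer nucleoli rather than overlap
      }
    }

    v_nlo <- sum(vapply(nucleoli, function(nl) 4 / 3 * pi * nl$radius^3, 0))
    v_nuc <- f * volume
    # cytoplasm density so the volume-weighted compartment mean equals dbar
    d_cyto <- dbar - f * cp$nucleus_density_offset -
      (v_nlo / volume) * cp$nucleolus_density_offset
    if (d_cyto <= 1.6)
      stop_labeled("sample_geometry",
                   "cytoplasm density fell below the usable range")
    densities <- c(cytoplasm = d_cyto,
                   nucleus = d_cyto + cp$nucleus_density_offset,
                   nucleolus = d_cyto + cp$nucleus_density_offset +
                     cp$nucleolus_density_offset)

    structure(
      list(label = cp$label, center = center, semiaxes = semiaxes,
           rotation = rot,
           nucleus = list(center = nuc_center, semiaxes = nuc_semiaxes,
                          rotation = rot),
           nucleoli = nucleoli,
           densities = densities,
           volume = volume, axis_ratio = q,
           target_sphericity = sph, mean_density = dbar,
           nucleus_volume = v_nuc, nucleolus_volume = v_nlo),
      class = "odt_geometry")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Analytic ground truth of a geometry
#'
#' Closed-form volume (fL), surface area (um^2; exact oblate-spheroid
#' formula), mean protein density (g/dL) and dry mass (pg) of a sampled
#' geometry, used as the oracle for the feature-extraction stage.
#'
#' @param geometry An `odt_geometry`.
#' @return Object of class `odt_ground_truth`.
#' @export
ground_truth <- function(geometry) {
  if (is.null(geometry$semiaxes)) {
    return(structure(list(label = geometry$label %||% NA_character_,
                          analytic_volume = 0, analytic_surface_area = 0,
                          analytic_mean_density = 0, analytic_dry_mass = 0),
                     class = "odt_ground_truth"))
  }
  V <- geometry$volume
  S <- oblate_area(geometry$semiaxes[1], geometry$axis_ratio)
  d <- geometry$mean_density
  structure(
    list(label = geometry$label,
         analytic_volume = V,
         analytic_surface_area = S,
         analytic_mean_density = d,
         analytic_dry_mass = d * V * 0.01),
    class = "odt_ground_truth")
}

#' @export
as.data.frame.odt_ground_truth <- function(x, ...) {
  data.frame(label = x$label, analytic_volume = x$analytic_volume,
             analytic_surface_area = x$analytic_surface_area,
             analytic_mean_density = x$analytic_mean_density,
             analytic_dry_mass = x$analytic_dry_mass,
             stringsAsFactors = FALSE)
}
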