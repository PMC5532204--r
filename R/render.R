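#' Construct a tomogram object
#'
#' @param values 3-D numeric array of refractive-index values.
#' @param grid [grid_spec()] describing shape and voxel pitch.
#' @param n_medium Refractive index of the surrounding medium.
#' @return Object of class `odt_tomogram`.
#' @export
tomogram <- function(values, grid, n_medium) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!all(dim(values) == grid$shape))
    stop_labeled("tomogram", "values shape does not match grid")
  if (!all(is.finite(values)))
    stop_labeled("tomogram", "non-finite RI values")
  structure(list(values = values, grid = grid, n_medium = n_medium),
            class = "odt_tomogram")
}

#' @export
print.odt_tomogram <- function(x, ...) {
  cat(sprintf(
    "<odt_tomogram> %d x %d x %d, pitch %.3g um, n_medium %.4f, RI in [%.4f, %.4f]\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    x$grid$voxel_pitch[1], x$n_medium, min(x$values), max(x$values)))
  invisible(x)
}

# squared ellipsoid coordinate of points (n x 3 world coords) for an
# ellipsoid (center, semiaxes, rotation); <= 1 means inside
ellipsoid_q2 <- function(pts, center, semiaxes, rotation) {
  loc <- sweep(pts, 2, center) %*% rotation  # = t(R) applied to rows
  (loc[, 1] / semiaxes[1])^2 + (loc[, 2] / semiaxes[2])^2 +
    (loc[, 3] / semiaxes[3])^2
}

#' Render a geometry into a refractive-index tomogram
#'
#' Voxels are assigned by centre-point membership (no partial-volume
#' averaging) so that voxel counts can be compared against analytic
#' expectations exactly. Background voxels take the medium RI; compartment
#' voxels take `n_medium + alpha*0.01*density`, the exact inverse of the
#' density conversion used by [protein_density_map()].
#'
#' @param geometry `odt_geometry` from [sample_geometry()], or `NULL` /
#'   a geometry without a cell for an empty (pure medium) volume.
#' @param grid [grid_spec()].
#' @param optics [optics_config()]; supplies `n_medium`.
#' @param alpha Refractive-index increment, mL/g (default 0.2).
#' @return A list with elements `tomogram` (`odt_tomogram`) and `truth`
#'   (`odt_ground_truth`).
#' @export
render_tomogram <- function(geometry, grid = grid_spec(),
                            optics = optics_config(), alpha = 0.2) {
  n0 <- optics$n_medium
  vals <- array(n0, dim = grid$shape)
  if (is.null(geometry) || is.null(geometry$semiaxes)) {
    truth <- ground_truth(list(label = geometry$label %||% NA_character_))
    return(list(tomogram = tomogram(vals, grid, n0), truth = truth))
  }

  rmax <- max(geometry$semiaxes)
  lo <- geometry$center - rmax
  hi <- geometry$center + rmax
  for (ax in 1:3) {
    if (lo[ax] < 0 || hi[ax] > grid$extent[ax])
      stop_labeled("render",
                   "geometry exceeds grid extent along axis ",
                   c("x", "y", "z")[ax])
  }

  conv <- ri_per_gdl(alpha)
  # voxel centres inside the cell bounding box
  idx <- lapply(1:3, function(ax) {
    co <- axis_coords(grid$shape[ax], grid$voxel_pitch[ax])
    which(co >= lo[ax] - grid$voxel_pitch[ax] &
            co <= hi[ax] + grid$voxel_pitch[ax])
  })
  co <- lapply(1:3, function(ax)
    axis_coords(grid$shape[ax], grid$voxel_pitch[ax])[idx[[ax]]])
  pts <- as.matrix(expand.grid(x = co[[1]], y = co[[2]], z = co[[3]]))

  q2 <- ellipsoid_q2(pts, geometry$center, geometry$semiaxes,
                     geometry$rotation)
  in_cell <- q2 <= 1
  dens <- rep(NA_real_, nrow(pts))
  dens[in_cell] <- geometry$densities[["cytoplasm"]]
  if (any(in_cell)) {
    qn <- ellipsoid_q2(pts[in_cell, , drop = FALSE],
                       geometry$nucleus$center,
                       geometry$nucleus$semiaxes,
                       geometry$nucleus$rotation)
    in_nuc <- qn <= 1
    dn <- dens[in_cell]
    dn[in_nuc] <- geometry$densities[["nucleus"]]
    if (length(geometry$nucleoli) > 0 && any(in_nuc)) {
      sub <- pts[in_cell, , drop = FALSE][in_nuc, , drop = FALSE]
      in_any_nlo <- rep(FALSE, nrow(sub))
      for (nl in geometry$nucleoli) {
        d2 <- (sub[, 1] - nl$center[1])^2 + (sub[, 2] - nl$center[2])^2 +
          (sub[, 3] - nl$center[3])^2
        in_any_nlo <- in_any_nlo | (d2 <= nl$radius^2)
      }
      dn_nuc <- dn[in_nuc]
      dn_nuc[in_any_nlo] <- geometry$densities[["nucleolus"]]
      dn[in_nuc] <- dn_nuc
    }
    dens[in_cell] <- dn
  }

  box <- array(n0, dim = vapply(idx, length, 0L))
  box[in_cell] <- n0 + conv * dens[in_cell]
  vals[idx[[1]], idx[[2]], idx[[3]]] <- box
  list(tomogram = tomogram(vals, grid, n0), truth = ground_truth(geometry))
}

#' Generate a labelled cohort of phantom tomograms
#'
#' Draws `n_per_class[label]` cells per class with per-cell seeds derived
#' deterministically from the master seed, renders each into a tomogram and
#' returns (or streams) the cells. Output is a pure function of the
#' arguments: the same seed gives bit-identical tomograms.
#'
#' @param n_per_class Named integer vector, e.g. `c(B = 149, CD4T = 95,
#'   CD8T = 112)`.
#' @param params Named list of [class_params()].
#' @param grid,optics Grid and optics configuration.
#' @param seed Master seed (integer).
#' @param handler Optional function `function(cell)` applied to each cell as
#'   it is produced; when given, only the handler results are kept, so large
#'   cohorts can be processed without holding every volume in memory.
#'   Each `cell` is a list with `cell_id`, `label`, `seed`, `tomogram`,
#'   `truth`.
#' @return List of cells (or of handler results), in class order.
#' @export
generate_cohort <- function(n_per_class, params = default_class_params(),
                            grid = grid_spec(), optics = optics_config(),
                            seed = 0, handler = NULL) {
  stopifnot(!is.null(names(n_per_class)), all(n_per_class >= 0))
  n_total <- sum(n_per_class)
  cell_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max - 1L, n_total))
  out <- vector("list", n_total)
  i <- 0L
  for (label in names(n_per_class)) {
    for (j in seq_len(n_per_class[[label]])) {
      i <- i + 1L
      geom <- sample_geometry(label, params, grid, seed = cell_seeds[i])
      rend <- render_tomogram(geom, grid, optics)
      cell <- list(cell_id = sprintf("%s_%03d", label, j), label = label,
                   seed = cell_seeds[i], tomogram = rend$tomogram,
                   truth = rend$truth)
      out[[i]] <- if (is.null(handler)) cell else handler(cell)
    }
  }
  out
}
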