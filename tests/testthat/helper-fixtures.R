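# Shared fixtures: all inputs are generated in code at test time.

# a bare uniform-density ellipsoid/sphere geometry (no internal structure)
make_plain_geometry <- function(radius = 2.5, density = 15,
                                center = NULL, grid = grid_spec(),
                                axis_ratio = 1) {
  center <- center %||% (grid$extent / 2)
  a <- radius
  structure(
    list(label = "X", center = center,
         semiaxes = c(a, a, axis_ratio * a), rotation = diag(3),
         nucleus = list(center = center, semiaxes = rep(1e-3, 3),
                        rotation = diag(3)),
         nucleoli = list(),
         densities = c(cytoplasm = density, nucleus = density,
                       nucleolus = density),
         volume = 4 / 3 * pi * axis_ratio * a^3, axis_ratio = axis_ratio,
         target_sphericity = 1, mean_density = density,
         nucleus_volume = 0, nucleolus_volume = 0),
    class = "odt_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tanh-edged sphere tomogram: a weak phantom whose spectrum is essentially
# band-limited, used for reconstruction round trips
make_smooth_sphere <- function(grid, optics, dn = 0.02, radius = 2.0,
                               edge = 0.1) {
  co <- lapply(1:3, function(ax)
    (seq_len(grid$shape[ax]) - 1) * grid$voxel_pitch[ax] -
      grid$extent[ax] / 2)
  r <- sqrt(outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+"))
  vals <- optics$n_medium + dn * 0.5 * (1 - tanh((r - radius) / edge))
  list(tomo = tomogram(vals, grid, optics$n_medium), r = r)
}

# independent brute-force k-NN voter implementing the same tie rule
brute_knn <- function(X, y, Q, k) {
  lv <- sort(unique(y))
  apply(Q, 1, function(q) {
    d <- sqrt(colSums((t(X) - q)^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    cls <- y[ord]
    dn <- d[ord]
    votes <- vapply(lv, function(l) sum(cls == l), 0L)
    cand <- lv[votes == max(votes)]
    if (length(cand) > 1) {
      ds <- vapply(cand, function(l) sum(dn[cls == l]), 0)
      cand <- cand[ds == min(ds)]
      if (length(cand) > 1) {
        dm <- vapply(cand, function(l) min(dn[cls == l]), 0)
        cand <- cand[dm == min(dm)]
      }
    }
    cand[1]
  })
}

# synthetic feature table with named feature columns drawn from class means
make_blob_table <- function(n_per_class, means, sd = 1, seed = 1,
                            columns = c("volume@1.340",
                                        "surface_area@1.340")) {
  withr::with_seed(seed, {
    rows <- lapply(names(n_per_class), function(l) {
      n <- n_per_class[[l]]
      df <- data.frame(cell_id = paste0(l, seq_len(n)), label = l,
                       stringsAsFactors = FALSE)
      for (j in seq_along(columns))
        df[[columns[j]]] <- rnorm(n, means[[l]][j], sd)
      df
    })
    do.call(rbind, rows)
  })
}
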