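grid <- grid_spec()
optics <- optics_config()

test_that("threshold grid default matches the published scheme", {
  g <- threshold_grid()
  expect_length(g, 20)
  expect_equal(g[1], 1.340)
  expect_equal(g[20], 1.378)
  expect_true(all(abs(diff(g) - 0.002) < 1e-9))
  expect_error(threshold_grid(1.35, 1.34, -0.002), "strictly increasing")
})

test_that("segmentation selects above-threshold voxels with cleanup", {
  rend <- render_tomogram(make_plain_geometry(radius = 2.0, density = 12))
  tomo <- rend$tomogram
  # threshold below all values: full grid, one component
  low <- segment_tomogram(tomogram(tomo$values + 1e-3, grid,
                                   tomo$n_medium), 1.3375)
  expect_true(low$valid)
  expect_true(all(low$mask))
  # above the maximum: empty and flagged
  hi <- segment_tomogram(tomo, 1.40)
  expect_false(hi$valid)
  expect_equal(sum(hi$mask), 0)
  # midway threshold: recovers the voxelized sphere (up to floating-point
  # ties for voxel centres sitting exactly on the analytic boundary)
  m <- segment_tomogram(tomo, (1.337 + 1.337 + 0.002 * 12) / 2)
  co <- (seq_len(96) - 1) * 0.1 - 4.8
  inside <- outer(outer(co^2, co^2, "+"), co^2, "+") <= 4
  expect_lt(abs(sum(m$mask) - sum(inside)), 10)
  expect_error(segment_tomogram(tomo, 1.33), "exceed the medium RI")
})

test_that("segmentation keeps the largest component and fills cavities", {
  vals <- array(1.337, c(24, 24, 24))
  vals[4:16, 4:16, 4:16] <- 1.36          # big cube
  vals[8:12, 8:12, 8:12] <- 1.337         # enclosed cavity
  vals[20:22, 20:22, 20:22] <- 1.36       # small separate blob
  tomo <- tomogram(vals, grid_spec(c(24, 24, 24), 0.1), 1.337)
  m <- segment_tomogram(tomo, 1.35)
  expect_equal(sum(m$mask), 13^3)  # cavity filled, blob dropped
  m2 <- segment_tomogram(tomo, 1.35, largest_only = FALSE,
                         fill_cavities = FALSE)
  expect_equal(sum(m2$mask), 13^3 - 5^3 + 3^3)
})

test_that("volume is voxel count times voxel volume and additive", {
  vals <- array(1.337, c(20, 20, 20))
  vals[1:10, , ] <- 1.36
  tomo <- tomogram(vals, grid_spec(c(20, 20, 20), 0.1), 1.337)
  m <- segment_tomogram(tomo, 1.35)
  expect_equal(measure_volume(m, tomo$grid), 10 * 20 * 20 * 0.001)
  # additivity over a plane split
  mA <- m; mA$mask[, 1:9, ] <- FALSE
  mB <- m; mB$mask[, 10:20, ] <- FALSE
  expect_equal(measure_volume(mA, tomo$grid) + measure_volume(mB, tomo$grid),
               measure_volume(m, tomo$grid))
})

test_that("surface area estimators behave as expected on digitized spheres", {
  for (r in c(1.5, 2.5, 3.5)) {
    rend <- render_tomogram(make_plain_geometry(radius = r))
    m <- segment_tomogram(rend$tomogram, 1.35)
    S_grad <- measure_surface_area(m, grid)
    S_vox <- measure_surface_area(m, grid, method = "voxel")
    expect_lt(abs(S_grad / (4 * pi * r^2) - 1), 0.03)
    expect_gt(S_vox, S_grad)  # staircase excess
  }
  # single voxel, paper-literal face counting
  vals <- array(1.337, c(16, 16, 16)); vals[8, 8, 8] <- 1.36
  tomo <- tomogram(vals, grid_spec(c(16, 16, 16), 0.1), 1.337)
  m1 <- segment_tomogram(tomo, 1.35)
  expect_equal(measure_surface_area(m1, tomo$grid, method = "voxel"), 0.06)
  # empty mask
  m0 <- segment_tomogram(tomo, 1.39)
  expect_true(is.na(measure_surface_area(m0, tomo$grid)))
})

test_that("sphericity formula is exact, homogeneous, and bounded on convex bodies", {
  r <- 2.5
  expect_equal(sphericity(4 * pi * r^2, 4 / 3 * pi * r^3), 1.0)
  # population means of B cells give the published sphericity scale
  expect_equal(round(sphericity(145.87, 133.43), 3), 0.866)
  expect_equal(sphericity(2 * 145.87, 133.43),
               sphericity(145.87, 133.43) / 2)
  expect_error(sphericity(-1, 10), "positive")
  # digitized convex bodies stay below 1 + epsilon under the gradient method
  for (q in c(1, 0.6)) {
    rend <- render_tomogram(make_plain_geometry(radius = 2.5,
                                                axis_ratio = q))
    m <- segment_tomogram(rend$tomogram, 1.35)
    sph <- sphericity(measure_surface_area(m, grid),
                      measure_volume(m, grid))
    expect_lt(sph, 1.02)
    expect_gt(sph, 0)
  }
})

test_that("density conversion inverts the rendering relation exactly", {
  conv <- conversion_params(n0 = 1.337, alpha = 0.2)
  tomo <- tomogram(array(1.369, c(16, 16, 16)),
                   grid_spec(c(16, 16, 16), 0.1), 1.337)
  C <- protein_density_map(tomo, conv)
  expect_equal(C[1], 16.0, tolerance = 1e-12)
  expect_equal(protein_density_map(
    tomogram(array(1.337, c(16, 16, 16)),
             grid_spec(c(16, 16, 16), 0.1), 1.337), conv)[1], 0)
  # rendered uniform phantom: interior density is exact
  rend <- render_tomogram(make_plain_geometry(radius = 2, density = 15))
  m <- segment_tomogram(rend$tomogram, 1.35)
  expect_equal(mean_protein_density(rend$tomogram, m), 15, tolerance = 1e-9)
})

test_that("two-compartment density averages by volume", {
  g <- sample_geometry("B", seed = 11)
  rend <- render_tomogram(g)
  m <- segment_tomogram(rend$tomogram, 1.340)
  got <- mean_protein_density(rend$tomogram, m)
  # voxel-weighted expectation from the rendered compartments
  expect_lt(abs(got / g$mean_density - 1), 0.02)
})

test_that("dry mass equals density times volume and is additive", {
  rend <- render_tomogram(make_plain_geometry(radius = 2.88, density = 15))
  tomo <- rend$tomogram
  m <- segment_tomogram(tomo, 1.35)
  V <- measure_volume(m, grid)
  M <- dry_mass(tomo, m, grid)
  expect_equal(M, mean_protein_density(tomo, m) * V * 0.01,
               tolerance = 1e-9)
  mA <- m; mA$mask[1:48, , ] <- FALSE
  mB <- m; mB$mask[49:96, , ] <- FALSE
  expect_equal(dry_mass(tomo, mA, grid) + dry_mass(tomo, mB, grid), M,
               tolerance = 1e-9)
  # scale check: uniform 15 g/dL over ~100 fL is ~15 pg
  expect_lt(abs(M / (15 * V * 0.01) - 1), 1e-9)
})

test_that("population means multiply to the published dry-mass scale", {
  # B cells: 15.43 g/dL x 133.43 fL x 0.01 = 20.59 pg, within 2% of the
  # published population-mean dry mass 20.28 pg (product of means vs mean
  # of products)
  expect_lt(abs(15.43 * 133.43 * 0.01 - 20.28) / 20.28, 0.02)
})

test_that("feature vectors have the right layout and monotonicity", {
  g <- sample_geometry("CD8T", seed = 5)
  rend <- render_tomogram(g)
  fv <- extract_features(rend$tomogram)
  expect_length(fv, 100)
  expect_true(all(grepl("@1\\.3", names(fv))))
  vols <- fv[paste0("volume@", sprintf("%.3f", threshold_grid()))]
  vols <- vols[!is.na(vols)]
  expect_true(all(diff(vols) <= 1e-12))
  # uniform sphere at RI 1.367: identical volume below, invalid above
  rend2 <- render_tomogram(make_plain_geometry(radius = 2, density = 15))
  fv2 <- extract_features(rend2$tomogram)
  v2 <- fv2[paste0("volume@", sprintf("%.3f", threshold_grid()))]
  expect_equal(length(unique(v2[!is.na(v2)])), 1L)
  expect_true(all(is.na(v2[threshold_grid() > 1.367])))
  valid <- attr(fv2, "valid")
  expect_false(all(valid))
})

test_that("features are invariant under axis permutation", {
  g <- sample_geometry("B", seed = 2)
  rend <- render_tomogram(g)
  fv <- extract_features(rend$tomogram, thresholds = c(1.340, 1.360))
  perm <- aperm(rend$tomogram$values, c(3, 1, 2))
  fvp <- extract_features(tomogram(perm, grid, rend$tomogram$n_medium),
                          thresholds = c(1.340, 1.360))
  expect_equal(fv, fvp, tolerance = 1e-9)
})

test_that("pooled t-test matches closed forms and flags known contrasts", {
  df <- data.frame(label = rep(c("a", "b"), each = 2),
                   `volume@1.340` = c(0, 0, 1, 1), check.names = FALSE)
  # zero pooled variance, unequal means: maximal evidence
  tt <- population_ttest(df, "volume@1.340")
  expect_equal(tt$p, 0)
  df2 <- data.frame(label = rep(c("a", "b"), each = 3),
                    `volume@1.340` = c(1, 2, 3, 1, 2, 3),
                    check.names = FALSE)
  tt2 <- population_ttest(df2, "volume@1.340")
  expect_equal(tt2$t, 0)
  expect_equal(tt2$p, 1)
  # hand-computed pooled t-test
  x <- c(1, 2, 3, 4); y <- c(4, 5, 7, 9)
  df3 <- data.frame(label = rep(c("a", "b"), each = 4),
                    `volume@1.340` = c(x, y), check.names = FALSE)
  tt3 <- population_ttest(df3, "volume@1.340")
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * 0.5)
  expect_equal(tt3$t, t_hand, tolerance = 1e-12)
  expect_equal(tt3$p, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  expect_equal(tt3$stars, "*")
})

test_that("B-vs-T volume contrast is significant at *** across seeds", {
  hits <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    vols <- withr::with_seed(s, list(
      B = rnorm(149, 133.43, 26.47),
      T = c(rnorm(95, 155.73, 35.14), rnorm(112, 152.77, 26.52))))
    df <- data.frame(label = rep(c("B", "T"), c(149, 207)),
                     `volume@1.340` = c(vols$B, vols$T),
                     check.names = FALSE)
    if (population_ttest(df, "volume@1.340")$stars == "***") hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_seeds)
})
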