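test_that("stratified split uses the floor rule deterministically", {
  df <- data.frame(cell_id = as.character(1:356),
                   label = rep(c("B", "CD4T", "CD8T"), c(149, 95, 112)),
                   x = rnorm(356))
  sp <- stratified_split(df, 0.7, seed = 1)
  expect_equal(as.vector(table(sp$train$label)[c("B", "CD4T", "CD8T")]),
               c(104, 66, 78))
  expect_equal(as.vector(table(sp$test$label)[c("B", "CD4T", "CD8T")]),
               c(45, 29, 34))
  expect_equal(nrow(sp$train) + nrow(sp$test), 356)
  expect_length(intersect(sp$train$cell_id, sp$test$cell_id), 0)
  # rounding contract at the edge
  df10 <- data.frame(cell_id = as.character(1:10),
                     label = rep("a", 10), x = rnorm(10))
  sp10 <- stratified_split(df10, 0.999, seed = 1)
  expect_equal(nrow(sp10$train), 9)
  expect_equal(nrow(sp10$test), 1)
  # determinism and seed sensitivity
  sp2 <- stratified_split(df, 0.7, seed = 1)
  expect_identical(sp$train$cell_id, sp2$train$cell_id)
  diffs <- vapply(1:100, function(s)
    !identical(stratified_split(df, 0.7, seed = s)$train$cell_id,
               sp$train$cell_id), TRUE)
  expect_gt(mean(diffs), 0.95)
  expect_error(stratified_split(df10[1, ], 0.7), ">= 2 members")
})

test_that("standardizer fits on training rows and inverts exactly", {
  X <- matrix(rnorm(80), 20, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
  # a row equal to the training mean maps to zero
  mu <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
  expect_lt(max(abs(apply_standardizer(std, mu))), 1e-12)
  # algebraic inversion
  expect_lt(max(abs(apply_standardizer(std, Z, invert = TRUE) - X)), 1e-12)
  # constant features are dropped with a warning; all-constant errors
  Xc <- cbind(X, const = 1)
  expect_warning(stdc <- fit_standardizer(Xc), "constant")
  expect_false("const" %in% stdc$columns)
  expect_error(suppressWarnings(
    fit_standardizer(matrix(1, 5, 2, dimnames = list(NULL, c("a", "b"))))),
    "constant")
  # missing entries imputed with the training median
  Xna <- X; Xna[1, 2] <- NA
  stdn <- fit_standardizer(Xna)
  z <- apply_standardizer(stdn, Xna)
  expect_true(all(is.finite(z)))
})

test_that("k-NN agrees with a brute-force voter on random instances", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      X <- matrix(rnorm(100), 50, 2)
      y <- sample(c("a", "b"), 50, replace = TRUE)
      Q <- matrix(rnorm(40), 20, 2)
      for (k in c(1, 3, 4, 5)) {
        expect_identical(knn_classify(X, y, Q, k),
                         unname(brute_knn(X, y, Q, k)))
      }
    }
  })
})

test_that("k-NN respects contracts at the edges", {
  X <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  y <- c("a", "a", "b")
  # query identical to a training point, k = 1
  expect_equal(knn_classify(X, y, X[3, , drop = FALSE], 1), "b")
  # k = n_train: global majority
  expect_equal(knn_classify(X, y, matrix(c(100, 100), 1), 3), "a")
  expect_error(knn_classify(X, y, matrix(0, 1, 3), 4), "dimension mismatch")
  expect_error(knn_classify(X, y, matrix(0, 1, 2), 10), "k exceeds")
  # repeated prediction is bit-identical
  Q <- matrix(rnorm(20), 10, 2)
  expect_identical(knn_classify(X, y, Q, 2), knn_classify(X, y, Q, 2))
})

test_that("subset enumeration matches the closed-form counts", {
  thr <- threshold_grid()
  expect_equal(nrow(enumerate_feature_subsets(thr[1])), 31)
  expect_equal(nrow(enumerate_feature_subsets(thr[1:2])), 1023)
  for (m in 2:4) {
    n <- nrow(enumerate_feature_subsets(thr[seq_len(m)]))
    expect_equal(n, m * 31 + choose(m, 2) * 31^2)
  }
  full <- enumerate_feature_subsets(thr)
  expect_equal(nrow(full), 183210)
  expect_equal(nrow(full), 20 * 31 + choose(20, 2) * (4^5 - 2 * 2^5 + 1))
  # no duplicates under the encoding
  key <- with(full, paste(t1, t2, mask1, mask2))
  expect_equal(anyDuplicated(key), 0L)
  # two-threshold subsets use both thresholds
  two <- full[!is.na(full$t2), ]
  expect_true(all(two$mask1 > 0 & two$mask2 > 0))
})

test_that("cross-validation separates blobs and is seed-stable", {
  blobs <- make_blob_table(c(a = 30, b = 30),
                           list(a = c(0, 0), b = c(10, 10)), seed = 3)
  cols <- c("volume@1.340", "surface_area@1.340")
  expect_equal(cross_validate(blobs, cols, k = 4, folds = 5, seed = 1), 1.0)
  a1 <- cross_validate(blobs, cols, k = 4, folds = 5, seed = 9)
  a2 <- cross_validate(blobs, cols, k = 4, folds = 5, seed = 9)
  expect_identical(a1, a2)
  expect_error(cross_validate(blobs[c(1:30, 31:33), ], cols, folds = 10),
               "fewer folds")
})

test_that("label permutation drives CV accuracy to chance", {
  blobs <- make_blob_table(c(a = 40, b = 40),
                           list(a = c(0, 0), b = c(8, 8)), seed = 5)
  cols <- c("volume@1.340", "surface_area@1.340")
  accs <- vapply(1:50, function(s) {
    perm <- blobs
    perm$label <- withr::with_seed(s, sample(perm$label))
    cross_validate(perm, cols, k = 4, folds = 5, seed = s)
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})

test_that("exhaustive search recovers planted informative features", {
  thr2 <- threshold_grid()[1:2]
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    tab <- withr::with_seed(s, {
      n <- 120
      df <- data.frame(cell_id = as.character(seq_len(n)),
                       label = rep(c("a", "b"), each = n / 2),
                       stringsAsFactors = FALSE)
      for (f in feature_families()) for (t in thr2)
        df[[sprintf("%s@%.3f", f, t)]] <- rnorm(n)
      shift <- ifelse(df$label == "a", 0, 3)
      df$`volume@1.340` <- df$`volume@1.340` + shift
      df$`dry_mass@1.342` <- df$`dry_mass@1.342` + shift
      df
    })
    sr <- select_best_subset(tab, thr2, k = 4, folds = 5, seed = s)
    expect_equal(nrow(sr$ledger), 1023)
    if (all(c("volume@1.340", "dry_mass@1.342") %in% sr$best_columns))
      hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_seeds)
})

test_that("search ties break towards fewer features, deterministically", {
  # one perfectly informative feature: every superset ties at accuracy 1
  tab <- make_blob_table(c(a = 30, b = 30), list(a = c(0, 0), b = c(50, 0)),
                         seed = 2,
                         columns = c("volume@1.340", "sphericity@1.340"))
  sr <- select_best_subset(tab, threshold_grid()[1], k = 4, folds = 5,
                           seed = 1)
  expect_equal(sr$cv_accuracy, 1.0)
  expect_equal(sr$best_columns, "volume@1.340")
})

test_that("subset selection ignores the test set entirely", {
  thr1 <- threshold_grid()[1]
  train <- make_blob_table(c(B = 40, CD4T = 40),
                           list(B = c(0, 0), CD4T = c(4, 0)), seed = 8,
                           columns = c("volume@1.340", "dry_mass@1.340"))
  # two adversarial "test" sets that would flip the informative column
  test1 <- make_blob_table(c(B = 20, CD4T = 20),
                           list(B = c(0, 0), CD4T = c(0, 9)), seed = 9,
                           columns = c("volume@1.340", "dry_mass@1.340"))
  test2 <- make_blob_table(c(B = 20, CD4T = 20),
                           list(B = c(9, 0), CD4T = c(0, 0)), seed = 10,
                           columns = c("volume@1.340", "dry_mass@1.340"))
  r1 <- run_task(train, test1, "multiclass", thr1, seed = 4)
  r2 <- run_task(train, test2, "multiclass", thr1, seed = 4)
  expect_identical(r1$search$best, r2$search$best)
  expect_identical(r1$train_confusion, r2$train_confusion)
})

test_that("classifier families compare on identical folds", {
  blobs <- make_blob_table(c(a = 40, b = 40),
                           list(a = c(0, 0), b = c(3, 3)), seed = 6)
  cols <- c("volume@1.340", "surface_area@1.340")
  cmp <- compare_classifiers(blobs, cols, folds = 5, seed = 2)
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$cv_accuracy >= 0 & cmp$cv_accuracy <= 1))
  # duplicate spec gives an identical accuracy
  cmp2 <- compare_classifiers(blobs, cols, specs = c("knn4", "knn4"),
                              folds = 5, seed = 2)
  expect_equal(cmp2$cv_accuracy[1], cmp2$cv_accuracy[2])
  expect_error(compare_classifiers(blobs, cols, specs = "svm"),
               "unknown classifier")
})

test_that("k-NN (k=4) holds its own among classifier families on calibrated cohorts", {
  grid <- grid_spec(c(48, 48, 48), 0.2)
  ft <- simulate_feature_table(c(B = 60, CD4T = 40, CD8T = 45),
                               grid = grid, seed = 11,
                               thresholds = c(1.342, 1.368))
  ft <- merge_labels(ft, "b_vs_t")
  # compare families on the search-selected feature subset, as in model
  # selection practice
  cols <- select_best_subset(ft, c(1.342, 1.368), seed = 1)$best_columns
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cmp <- compare_classifiers(ft, cols, folds = 5, seed = s)
    knn4 <- cmp$cv_accuracy[cmp$spec == "knn4"]
    if (knn4 >= median(cmp$cv_accuracy)) hits <- hits + 1
  }
  expect_gte(hits, 0.7 * n_seeds)
})

test_that("family restriction filters columns and supports the ablation", {
  cols <- as.vector(outer(feature_families(),
                          sprintf("%.3f", threshold_grid()),
                          function(f, t) paste0(f, "@", t)))
  df <- data.frame(cell_id = "c1", label = "B", check.names = FALSE)
  for (cl in cols) df[[cl]] <- 1
  morpho <- restrict_families(df, c("surface_area", "volume", "sphericity"))
  expect_equal(ncol(morpho), 2 + 60)
  expect_identical(names(restrict_families(df, feature_families())),
                   names(df))
  expect_error(restrict_families(df, "texture"), "unknown feature family")
})

test_that("dropping the biochemical families loses accuracy when density carries signal", {
  cols5 <- paste0(feature_families(), "@1.340")
  wins <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    # density/mass informative, morphology uninformative
    tab <- make_blob_table(
      c(a = 40, b = 40),
      list(a = c(0, 0, 0, 0, 0), b = c(0, 0, 0, 2.5, 2.5)),
      seed = s, columns = cols5)
    full <- cross_validate(tab, cols5, k = 4, folds = 5, seed = s)
    morpho <- cross_validate(
      restrict_families(tab, c("surface_area", "volume", "sphericity")),
      cols5[1:3], k = 4, folds = 5, seed = s)
    if (morpho <= full) wins <- wins + 1
  }
  expect_gte(wins, 0.8 * n_seeds)
})
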