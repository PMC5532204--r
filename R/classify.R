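feature_columns <- function(dataset) {
  cols <- setdiff(names(dataset)[vapply(dataset, is.numeric, TRUE)],
                  "cell_id")
  grep("^analytic_", cols, value = TRUE, invert = TRUE)
}

#' Stratified train/test split
#'
#' Per class, `floor(fraction * n)` rows go to training and the remainder to
#' test; the partition is deterministic for a given seed. With class sizes
#' 149/95/112 and the default fraction 0.7 this gives training sets of
#' 104/66/78 cells.
#'
#' @param dataset `data.frame` with a `label` column.
#' @param train_fraction Training fraction in (0, 1) (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
stratified_split <- function(dataset, train_fraction = 0.7, seed = 0) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labs <- unique(dataset$label)
  counts <- table(dataset$label)
  if (any(counts < 2))
    stop_labeled("split", "every class needs >= 2 members")
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(labs, function(l) {
      rows <- which(dataset$label == l)
      n_tr <- floor(train_fraction * length(rows))
      sample(rows, n_tr)
    }))
  })
  list(train = dataset[sort(idx_train), , drop = FALSE],
       test = dataset[setdiff(seq_len(nrow(dataset)), idx_train), ,
                      drop = FALSE])
}

#' Fit a feature standardizer on training rows
#'
#' Records, per feature column, the training median (used to impute missing
#' entries), mean and SD. Constant features are dropped with a warning.
#' Standardization statistics always come from training rows only; test
#' rows are transformed with the training statistics.
#'
#' @param train Training `data.frame` (or numeric matrix) of features.
#' @param columns Feature columns (default: all numeric feature columns).
#' @return Object of class `odt_standardizer`.
#' @export
fit_standardizer <- function(train, columns = NULL) {
  if (is.data.frame(train)) {
    columns <- columns %||% feature_columns(train)
    X <- as.matrix(train[, columns, drop = FALSE])
  } else {
    X <- as.matrix(train)
    columns <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  }
  if (nrow(X) == 0) stop_labeled("standardize", "empty training set")
  med <- apply(X, 2, function(v) stats::median(v, na.rm = TRUE))
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  keep <- sg > 1e-12
  if (!any(keep)) stop_labeled("standardize", "all features are constant")
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(columns[!keep], collapse = ", "))
  structure(list(columns = columns[keep], median = med[keep],
                 mean = mu[keep], sd = sg[keep]),
            class = "odt_standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param std `odt_standardizer`.
#' @param rows `data.frame` or matrix containing the standardizer's columns.
#' @param invert Undo the transformation instead (default FALSE).
#' @return Numeric matrix of transformed feature columns.
#' @export
apply_standardizer <- function(std, rows, invert = FALSE) {
  X <- if (is.data.frame(rows)) as.matrix(rows[, std$columns, drop = FALSE])
  else as.matrix(rows)[, std$columns, drop = FALSE]
  if (invert)
    return(sweep(sweep(X, 2, std$sd, "*"), 2, std$mean, "+"))
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- std$median[j]
  sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
}

#' k-nearest-neighbour classification
#'
#' Euclidean k-NN on (already standardized) features with a fully
#' deterministic tie rule: majority vote among the k nearest neighbours
#' (neighbour distance ties broken by training-row order); vote ties broken
#' by the smallest summed neighbour distance among the tied classes, then by
#' the closest single neighbour, then by lexicographic label order.
#'
#' @param train Numeric matrix of training features.
#' @param labels Training labels (character or factor).
#' @param queries Numeric matrix of query features (same columns).
#' @param k Neighbour count (default 4); must not exceed the training size.
#' @return Character vector of predicted labels.
#' @export
knn_classify <- function(train, labels, queries, k = 4) {
  train <- as.matrix(train); queries <- as.matrix(queries)
  if (ncol(train) != ncol(queries))
    stop_labeled("knn", "feature dimension mismatch (",
                 ncol(train), " vs ", ncol(queries), ")")
  if (k > nrow(train))
    stop_labeled("knn", "k exceeds the training-set size")
  lv <- sort(unique(as.character(labels)))
  yi <- match(as.character(labels), lv)
  pred <- knn_predict_cpp(train, yi, queries, as.integer(k), length(lv))
  lv[pred]
}

#' Enumerate the admissible feature subsets
#'
#' Every nonempty set of (family, threshold) features that uses exactly one
#' or exactly two distinct thresholds from the grid. Subsets are encoded
#' compactly, one row each: `t1`, `t2` (threshold values, `t2 = NA` for
#' single-threshold subsets) and 5-bit family masks `mask1`, `mask2`
#' (bit b set = family `feature_families()[b+1]` at that threshold; for
#' two-threshold subsets both masks are nonzero). The enumeration order is
#' deterministic: single thresholds in grid order with ascending mask, then
#' threshold pairs (i < j) with ascending `(mask1, mask2)`.
#'
#' With the default 20-threshold grid the enumeration has
#' 20*31 + C(20,2)*31^2 = 183,210 rows.
#'
#' @param thresholds Threshold vector (default [threshold_grid()]).
#' @param families Feature family names (default all five).
#' @return `data.frame` with one row per subset.
#' @export
enumerate_feature_subsets <- function(thresholds = threshold_grid(),
                                      families = feature_families()) {
  stopifnot(length(thresholds) >= 1, length(families) >= 1)
  nf <- length(families)
  masks <- seq_len(2^nf - 1)
  single <- data.frame(
    t1 = rep(thresholds, each = length(masks)),
    t2 = NA_real_,
    mask1 = rep(masks, times = length(thresholds)),
    mask2 = 0L)
  if (length(thresholds) >= 2) {
    pr <- utils::combn(seq_along(thresholds), 2)
    npair <- ncol(pr)
    grid2 <- expand.grid(mask2 = masks, mask1 = masks)  # mask1 slowest
    pairs <- data.frame(
      t1 = rep(thresholds[pr[1, ]], each = nrow(grid2)),
      t2 = rep(thresholds[pr[2, ]], each = nrow(grid2)),
      mask1 = rep(grid2$mask1, times = npair),
      mask2 = rep(grid2$mask2, times = npair))
    out <- rbind(single, pairs)
  } else out <- single
  attr(out, "families") <- families
  out
}

# column names of one encoded subset row
subset_column_names <- function(row, families = feature_families()) {
  bits <- function(mask) which(bitwAnd(mask, 2^(seq_along(families) - 1)) > 0)
  nms <- feature_name(families[bits(row$mask1)], row$t1)
  if (!is.na(row$t2) && row$mask2 > 0)
    nms <- c(nms, feature_name(families[bits(row$mask2)], row$t2))
  nms
}

subset_size <- function(subsets) {
  popcount <- function(m) {
    n <- integer(length(m))
    while (any(m > 0)) { n <- n + (m %% 2L); m <- m %/% 2L }
    n
  }
  popcount(as.integer(subsets$mask1)) + popcount(as.integer(subsets$mask2))
}

make_folds <- function(labels, folds, seed) {
  f <- integer(length(labels))
  withr::with_seed(seed, {
    for (l in unique(labels)) {
      rows <- which(labels == l)
      rows <- sample(rows)
      f[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  f
}

# Mean CV accuracy of every encoded subset. Per fold the candidate columns
# are imputed and standardized on the fold-training part only, then all
# subsets are scored in compiled code.
cv_subset_accuracies <- function(train, subsets, k = 4, folds = 5, seed = 0,
                                 families = feature_families()) {
  labels <- as.character(train$label)
  lv <- sort(unique(labels))
  yi <- match(labels, lv)
  cols_by_subset <- lapply(seq_len(nrow(subsets)), function(i)
    subset_column_names(subsets[i, ], families))
  all_cols <- intersect(unique(unlist(cols_by_subset)), names(train))
  if (length(all_cols) == 0)
    stop_labeled("cv", "none of the enumerated features are in the table")
  # subsets touching columns absent from the table score NA
  cols_by_subset <- lapply(cols_by_subset, function(nms)
    if (all(nms %in% all_cols)) nms else NA)
  fold_id <- make_folds(labels, folds, seed)
  if (min(table(labels)) < folds)
    stop_labeled("cv", "a fold would miss a class; use fewer folds")
  acc <- matrix(NA_real_, nrow(subsets), folds)
  for (f in seq_len(folds)) {
    tr <- train[fold_id != f, , drop = FALSE]
    te <- train[fold_id == f, , drop = FALSE]
    std <- suppressWarnings(fit_standardizer(tr, all_cols))
    Xtr <- apply_standardizer(std, tr)
    Xte <- apply_standardizer(std, te)
    col_idx <- lapply(cols_by_subset, function(nms) {
      if (length(nms) == 1 && is.na(nms[1])) return(NA_integer_)
      idx <- match(nms, std$columns)
      if (anyNA(idx) || length(idx) == 0) NA_integer_ else idx
    })
    usable <- !vapply(col_idx, function(x) anyNA(x), TRUE)
    yi_tr <- match(tr$label, lv)
    yi_te <- match(te$label, lv)
    if (any(usable)) {
      acc[usable, f] <- knn_subset_accuracy_cpp(
        Xtr, yi_tr, Xte, yi_te, col_idx[usable], as.integer(k), length(lv))
    }
  }
  rowMeans(acc)
}

#' Cross-validated accuracy of one feature subset
#'
#' Stratified k-fold cross-validation (default 5 folds) with per-fold
#' imputation and standardization fitted on the fold-training part, scored
#' by k-NN accuracy; deterministic for a given seed.
#'
#' @param train Training `data.frame` with `label` and feature columns.
#' @param columns Character vector of feature column names to use.
#' @param k Neighbour count (default 4).
#' @param folds Fold count (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return Mean accuracy over folds.
#' @export
cross_validate <- function(train, columns, k = 4, folds = 5, seed = 0) {
  stopifnot(folds >= 2)
  labels <- as.character(train$label)
  lv <- sort(unique(labels))
  fold_id <- make_folds(labels, folds, seed)
  if (min(table(labels)) < folds)
    stop_labeled("cv", "a fold would miss a class; use fewer folds")
  accs <- vapply(seq_len(folds), function(f) {
    tr <- train[fold_id != f, , drop = FALSE]
    te <- train[fold_id == f, , drop = FALSE]
    std <- suppressWarnings(fit_standardizer(tr, columns))
    pred <- knn_classify(apply_standardizer(std, tr), tr$label,
                         apply_standardizer(std, te), k)
    mean(pred == te$label)
  }, 0)
  mean(accs)
}

#' Exhaustive feature-subset search
#'
#' Evaluates every subset from [enumerate_feature_subsets()] by
#' cross-validated k-NN accuracy and returns the winner. Accuracy ties are
#' broken in favour of fewer features, then by enumeration order (which is
#' lexicographic in the subset encoding).
#'
#' @param train Training `data.frame`.
#' @param thresholds Threshold grid spanned by the feature columns.
#' @param k,folds,seed Cross-validation settings.
#' @return Object of class `odt_search`: `best` (encoded subset row),
#'   `best_columns`, `cv_accuracy`, and `ledger` (all subsets with their CV
#'   accuracies, ranked).
#' @export
select_best_subset <- function(train, thresholds = threshold_grid(),
                               k = 4, folds = 5, seed = 0) {
  subsets <- enumerate_feature_subsets(thresholds)
  acc <- cv_subset_accuracies(train, subsets, k, folds, seed)
  if (all(is.na(acc)))
    stop_labeled("search", "no evaluable feature subset")
  size <- subset_size(subsets)
  ord <- order(-acc, size, seq_len(nrow(subsets)), na.last = TRUE)
  best_i <- ord[1]
  ledger <- subsets
  ledger$n_features <- size
  ledger$cv_accuracy <- acc
  ledger <- ledger[ord, , drop = FALSE]
  structure(
    list(best = subsets[best_i, , drop = FALSE],
         best_columns = subset_column_names(subsets[best_i, ]),
         cv_accuracy = acc[best_i],
         ledger = ledger),
    class = "odt_search")
}

#' @export
print.odt_search <- function(x, ...) {
  cat(sprintf("<odt_search> best CV accuracy %.4f with %d feature(s):\n",
              x$cv_accuracy, length(x$best_columns)))
  cat(" ", paste(x$best_columns, collapse = ", "), "\n")
  invisible(x)
}

classifier_registry <- function() {
  list(
    knn4 = list(
      fit = function(X, y) list(X = X, y = y),
      predict = function(m, X) knn_classify(m$X, m$y, X, k = 4)),
    knn6 = list(
      fit = function(X, y) list(X = X, y = y),
      predict = function(m, X) knn_classify(m$X, m$y, X, k = 6)),
    lda = list(
      fit = function(X, y) MASS::lda(X, grouping = factor(y)),
      predict = function(m, X) as.character(stats::predict(m, X)$class)),
    qda = list(
      fit = function(X, y) MASS::qda(X, grouping = factor(y)),
      predict = function(m, X) as.character(stats::predict(m, X)$class)),
    naive_bayes = list(
      fit = function(X, y) e1071::naiveBayes(X, factor(y)),
      predict = function(m, X) as.character(stats::predict(m, X))),
    decision_tree = list(
      fit = function(X, y) {
        d <- as.data.frame(X); d$.y <- factor(y)
        rpart::rpart(.y ~ ., data = d, method = "class")
      },
      predict = function(m, X)
        as.character(stats::predict(m, as.data.frame(X), type = "class")))
  )
}

#' Compare classifier families by cross-validation
#'
#' Scores a fixed feature subset with several classifier families (k-NN with
#' k = 4 and k = 6, linear and quadratic discriminant analysis, naive Bayes,
#' decision tree) on identical stratified folds, with per-fold
#' standardization.
#'
#' @param train Training `data.frame`.
#' @param columns Feature columns to use.
#' @param specs Character vector of registered classifier names (default:
#'   all six).
#' @param folds,seed Cross-validation settings.
#' @return `data.frame` with one row per spec and its CV accuracy.
#' @export
compare_classifiers <- function(train, columns,
                                specs = c("knn4", "knn6", "lda", "qda",
                                          "naive_bayes", "decision_tree"),
                                folds = 5, seed = 0) {
  reg <- classifier_registry()
  unknown <- setdiff(specs, names(reg))
  if (length(unknown) > 0)
    stop_labeled("compare", "unknown classifier spec: ",
                 paste(unknown, collapse = ", "))
  labels <- as.character(train$label)
  fold_id <- make_folds(labels, folds, seed)
  acc <- vapply(specs, function(s) {
    cl <- reg[[s]]
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- train[fold_id != f, , drop = FALSE]
      te <- train[fold_id == f, , drop = FALSE]
      std <- suppressWarnings(fit_standardizer(tr, columns))
      m <- cl$fit(apply_standardizer(std, tr), tr$label)
      mean(cl$predict(m, apply_standardizer(std, te)) == te$label)
    }, 0)
    mean(fold_acc)
  }, 0)
  data.frame(spec = specs, cv_accuracy = as.numeric(acc),
             stringsAsFactors = FALSE)
}

#' Restrict a feature table to selected families
#'
#' Keeps `cell_id`/`label` plus the columns of the named feature families at
#' all thresholds; used e.g. for the morphology-only ablation (surface area,
#' volume, sphericity).
#'
#' @param dataset Feature `data.frame`.
#' @param families Nonempty subset of [feature_families()].
#' @return Filtered `data.frame`.
#' @export
restrict_families <- function(dataset, families) {
  unknown <- setdiff(families, feature_families())
  if (length(unknown) > 0 || length(families) == 0)
    stop_labeled("restrict", "unknown feature family: ",
                 paste(unknown, collapse = ", "))
  keep_meta <- intersect(c("cell_id", "label"), names(dataset))
  patt <- paste0("^(", paste(families, collapse = "|"), ")@")
  keep <- grep(patt, names(dataset), value = TRUE)
  dataset[, c(keep_meta, keep), drop = FALSE]
}
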