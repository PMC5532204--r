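#' Task label mapping
#'
#' The three classification tasks: `b_vs_t` merges the two T-cell classes
#' into one `T` class; `cd4_vs_cd8` drops B cells; `multiclass` keeps all
#' three labels.
#'
#' @param task One of `"b_vs_t"`, `"cd4_vs_cd8"`, `"multiclass"`.
#' @param dataset `data.frame` with a `label` column over
#'   `{B, CD4T, CD8T}`.
#' @return The dataset with labels merged/filtered for the task.
#' @export
merge_labels <- function(dataset, task = c("b_vs_t", "cd4_vs_cd8",
                                           "multiclass")) {
  task <- match.arg(task)
  known <- c("B", "CD4T", "CD8T")
  bad <- setdiff(unique(dataset$label), known)
  if (length(bad) > 0)
    stop_labeled("merge", "unmapped label(s): ", paste(bad, collapse = ", "))
  if (task == "b_vs_t") {
    dataset$label <- ifelse(dataset$label == "B", "B", "T")
  } else if (task == "cd4_vs_cd8") {
    dataset <- dataset[dataset$label != "B", , drop = FALSE]
  }
  dataset
}

task_classes <- function(task) {
  switch(task,
         b_vs_t = c("B", "T"),
         cd4_vs_cd8 = c("CD4T", "CD8T"),
         multiclass = c("B", "CD4T", "CD8T"))
}

#' Build a confusion matrix
#'
#' Rows are true (input) classes, columns predicted (output) classes.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_order Class ordering for rows/columns (default: sorted
#'   union of the true labels).
#' @return Integer matrix of class `odt_confusion`.
#' @export
build_confusion <- function(true_labels, predicted_labels,
                            class_order = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop_labeled("confusion", "label vectors differ in length")
  class_order <- class_order %||% sort(unique(as.character(true_labels)))
  foreign <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(foreign) > 0)
    stop_labeled("confusion", "label(s) outside class order: ",
                 paste(foreign, collapse = ", "))
  m <- table(factor(true_labels, levels = class_order),
             factor(predicted_labels, levels = class_order))
  m <- unclass(m)
  dimnames(m) <- list(true = class_order, predicted = class_order)
  structure(m, class = c("odt_confusion", class(m)))
}

#' @export
print.odt_confusion <- function(x, ...) {
  print(matrix(as.vector(x), nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

as_confusion <- function(counts, classes) {
  m <- matrix(as.numeric(counts), length(classes), length(classes),
              byrow = TRUE, dimnames = list(true = classes,
                                            predicted = classes))
  structure(m, class = c("odt_confusion", class(m)))
}

#' Per-class sensitivity
#'
#' True positives over all positive inputs: `100 * diagonal / row sum`, in
#' percent.
#'
#' @param m Confusion matrix.
#' @param class Class name (row); default: all classes.
#' @return Named numeric vector of percentages (`NaN` for an empty row).
#' @export
sensitivity <- function(m, class = NULL) {
  classes <- class %||% rownames(m)
  out <- vapply(classes, function(cl)
    100 * m[cl, cl] / sum(m[cl, ]), 0)
  stats::setNames(out, classes)
}

#' Per-class specificity
#'
#' True negatives over all negative inputs, one-vs-rest: among rows other
#' than `class`, the fraction not predicted as `class`, in percent.
#'
#' @inheritParams sensitivity
#' @return Named numeric vector of percentages.
#' @export
specificity <- function(m, class = NULL) {
  classes <- class %||% rownames(m)
  out <- vapply(classes, function(cl) {
    neg <- setdiff(rownames(m), cl)
    tot <- sum(m[neg, , drop = FALSE])
    100 * (tot - sum(m[neg, cl])) / tot
  }, 0)
  stats::setNames(out, classes)
}

#' Overall accuracy
#'
#' `100 * trace / total`, in percent.
#'
#' @param m Confusion matrix.
#' @return Percentage.
#' @export
overall_accuracy <- function(m) {
  tot <- sum(m)
  if (tot == 0) stop_labeled("accuracy", "empty confusion matrix")
  100 * sum(diag(as.matrix(m))) / tot
}

#' Metrics report for a confusion matrix
#'
#' @param m Confusion matrix.
#' @return List with per-class `sensitivity`, `specificity` and
#'   `overall_accuracy` (percent, full precision; round to 2 decimals for
#'   display).
#' @export
metrics_report <- function(m) {
  list(sensitivity = sensitivity(m),
       specificity = specificity(m),
       overall_accuracy = overall_accuracy(m))
}

#' Reference confusion matrices of the lymphocyte classification study
#'
#' The published training/test confusion-matrix counts for the three
#' lymphocyte discrimination tasks (B vs merged T; CD4 vs CD8; all three
#' classes), bundled so the reported sensitivities, specificities and
#' overall accuracies can be recomputed from the raw counts.
#'
#' @return Nested list: `$<task>$train` / `$<task>$test`, each an
#'   `odt_confusion`.
#' @export
reference_confusions <- function() {
  list(
    b_vs_t = list(
      train = as_confusion(c(96, 8,
                             9, 135), c("B", "T")),
      test = as_confusion(c(42, 3,
                            8, 55), c("B", "T"))),
    cd4_vs_cd8 = list(
      train = as_confusion(c(54, 12,
                             6, 71), c("CD4T", "CD8T")),
      test = as_confusion(c(25, 4,
                            6, 29), c("CD4T", "CD8T"))),
    multiclass = list(
      train = as_confusion(c(89, 6, 9,
                             8, 49, 9,
                             7, 9, 62), c("B", "CD4T", "CD8T")),
      test = as_confusion(c(39, 1, 5,
                            2, 21, 6,
                            2, 10, 22), c("B", "CD4T", "CD8T")))
  )
}

#' Train, apply and score a classification task end-to-end
#'
#' Merges labels according to the task, runs the exhaustive subset search
#' on the training set, fits the final k-NN classifier on all training rows,
#' and reports confusion matrices and metrics for both the training set
#' (self-prediction by the trained classifier; each training point may count
#' itself among its neighbours unless `include_self = FALSE`) and the test
#' set.
#'
#' @param train,test Feature `data.frame`s from the same schema.
#' @param task Task name, see [merge_labels()].
#' @param thresholds Threshold grid spanned by the feature columns.
#' @param k,folds,seed Classifier and cross-validation settings.
#' @param include_self Count a training point as its own neighbour when
#'   scoring the training set (default TRUE).
#' @return List of class `odt_task_report`: `task`, `search`,
#'   `train_confusion`, `test_confusion`, `train_metrics`, `test_metrics`.
#' @export
run_task <- function(train, test, task = "b_vs_t",
                     thresholds = threshold_grid(), k = 4, folds = 5,
                     seed = 0, include_self = TRUE) {
  train <- merge_labels(train, task)
  test <- merge_labels(test, task)
  search <- select_best_subset(train, thresholds, k, folds, seed)
  cols <- search$best_columns
  std <- suppressWarnings(fit_standardizer(train, cols))
  Xtr <- apply_standardizer(std, train)
  Xte <- apply_standardizer(std, test)
  if (include_self) {
    pred_tr <- knn_classify(Xtr, train$label, Xtr, k)
  } else {
    pred_tr <- vapply(seq_len(nrow(Xtr)), function(i)
      knn_classify(Xtr[-i, , drop = FALSE], train$label[-i],
                   Xtr[i, , drop = FALSE], k), "")
  }
  pred_te <- knn_classify(Xtr, train$label, Xte, k)
  classes <- task_classes(task)
  cm_tr <- build_confusion(train$label, pred_tr, classes)
  cm_te <- build_confusion(test$label, pred_te, classes)
  structure(
    list(task = task, search = search,
         train_confusion = cm_tr, test_confusion = cm_te,
         train_metrics = metrics_report(cm_tr),
         test_metrics = metrics_report(cm_te)),
    class = "odt_task_report")
}

#' @export
print.odt_task_report <- function(x, ...) {
  cat(sprintf("<odt_task_report> task %s\n", x$task))
  cat(sprintf("  features: %s\n",
              paste(x$search$best_columns, collapse = ", ")))
  cat(sprintf("  training accuracy %.2f%%, test accuracy %.2f%%\n",
              x$train_metrics$overall_accuracy,
              x$test_metrics$overall_accuracy))
  invisible(x)
}
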