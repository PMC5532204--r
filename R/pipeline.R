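#' Run the full phantom-to-report pipeline from a declarative config
#'
#' Stages: phantom cohort generation (+ feature extraction; optionally a
#' holography/reconstruction round trip per cell), stratified train/test
#' split, and per-task subset selection, training and evaluation. All
#' randomness derives from the single `seed` in the config, so a rerun with
#' the same config reproduces every numeric output.
#'
#' Config keys (YAML file or named list): `seed`; `out_dir`; `cohort`
#' (named counts, e.g. `B: 15`); `grid` (`shape`, `pitch`); `thresholds`
#' (`from`, `to`, `by`); `tasks` (subset of b_vs_t / cd4_vs_cd8 /
#' multiclass); `classifier` (`k`, `folds`); `train_fraction`;
#' `reconstruct` (logical: push every phantom through hologram synthesis
#' and tomographic reconstruction before feature extraction — slow, for
#' validation runs); `recon` (`n_angles`, `tilt_deg`, `iterations`).
#' Unknown keys are rejected.
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisible list with `features`, `split`, `reports`; artifacts
#'   are written under `out_dir` when it is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "cohort", "grid", "thresholds", "tasks",
             "classifier", "train_fraction", "reconstruct", "recon")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop_labeled("config", "unknown config key(s): ",
                 paste(unknown, collapse = ", "))
  seed <- config$seed %||% 0
  counts <- unlist(config$cohort %||% list(B = 15, CD4T = 15, CD8T = 15))
  grid <- grid_spec(config$grid$shape %||% c(96, 96, 96),
                    config$grid$pitch %||% 0.1)
  optics <- optics_config()
  thr <- do.call(threshold_grid, config$thresholds %||% list())
  tasks <- config$tasks %||% c("b_vs_t", "cd4_vs_cd8", "multiclass")
  k <- config$classifier$k %||% 4
  folds <- config$classifier$folds %||% 5
  frac <- config$train_fraction %||% 0.7

  message("stage phantoms: ", sum(counts), " cells, grid ",
          paste(grid$shape, collapse = "x"), ", seed ", seed)
  if (isTRUE(config$reconstruct)) {
    n_ang <- config$recon$n_angles %||% 40
    tilt <- config$recon$tilt_deg %||% 55
    iters <- config$recon$iterations %||% 100
    dirs <- illumination_directions(n_ang, tilt, optics)
    handler <- function(cell) {
      stk <- simulate_hologram_stack(cell$tomogram, dirs, optics)
      rec <- reconstruct_tomogram(stk$holograms, stk$background, optics,
                                  grid, recon_settings(iterations = iters))
      fv <- extract_features(rec, thr)
      cbind(data.frame(cell_id = cell$cell_id, label = cell$label,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(fv), check.names = FALSE),
            as.data.frame(cell$truth)[-1])
    }
    rows <- generate_cohort(counts, default_class_params(), grid, optics,
                            seed, handler = handler)
    features <- do.call(rbind, rows)
  } else {
    features <- simulate_feature_table(counts, grid = grid, optics = optics,
                                       seed = seed, thresholds = thr)
  }

  message("stage split: fraction ", frac)
  split <- stratified_split(features, frac, seed = seed + 1)

  reports <- list()
  for (task in tasks) {
    message("stage classify/evaluate: ", task,
            " (k = ", k, ", folds = ", folds, ")")
    reports[[task]] <- run_task(split$train, split$test, task, thr,
                                k = k, folds = folds, seed = seed + 2)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features,
                        file.path(config$out_dir, "features.csv"))
    rep_json <- lapply(reports, function(r) list(
      task = r$task,
      selected_features = r$search$best_columns,
      cv_accuracy = r$search$cv_accuracy,
      train_confusion = as.data.frame(unclass(r$train_confusion)),
      test_confusion = as.data.frame(unclass(r$test_confusion)),
      train_metrics = r$train_metrics,
      test_metrics = r$test_metrics))
    jsonlite::write_json(list(config = config, reports = rep_json),
                         file.path(config$out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(features = features, split = split, reports = reports))
}
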