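#' Run configuration for the study pipelines
#'
#' Collects every setting the baseline and hybrid experiments need, with
#' exactly one input source: either paths to prediction/panel CSVs or a
#' simulation preset. Every report embeds this configuration so any run is
#' reproducible from its output.
#'
#' @param predictions_csv,panel_csv Paths to the input CSVs, or `NULL`.
#' @param preset `"dissociation"` to use the shipped synthetic fixture
#'   instead of files.
#' @param s Partition parameter (> 2), default 4.
#' @param iterations Monte-Carlo trials for the hybrid ensemble,
#'   default 1000.
#' @param seed Integer seed, default 1.
#' @param grid_size Number of thresholds between 1 and 0, default 201.
#' @param min_frac Completion fraction for rater inclusion, default 0.84
#'   (126 of 150 images).
#' @param output_dir Directory for written artifacts, or `NULL` to skip
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(predictions_csv = NULL, panel_csv = NULL,
                       preset = NULL, s = 4, iterations = 1000,
                       seed = 1L, grid_size = 201, min_frac = 0.84,
                       output_dir = NULL) {
  has_files <- !is.null(predictions_csv) && !is.null(panel_csv)
  if (has_files == !is.null(preset)) {
    abort("Provide exactly one input source: both CSV paths, or a preset.",
          class = "hybridroc_input_error")
  }
  if (!is.null(preset) && !identical(preset, "dissociation")) {
    abort("The only available preset is \"dissociation\".",
          class = "hybridroc_input_error")
  }
  structure(
    list(predictions_csv = predictions_csv, panel_csv = panel_csv,
         preset = preset, s = s, iterations = as.integer(iterations),
         seed = as.integer(seed), grid_size = as.integer(grid_size),
         min_frac = min_frac, output_dir = output_dir),
    class = "run_config")
}

# Internal: resolve the configured input source to predictions + panel.
load_inputs <- function(config) {
  if (!is.null(config$preset)) {
    sim <- make_dissociation_fixture(seed = config$seed)
    list(predictions = sim$predictions, panel = sim$panel)
  } else {
    list(predictions = read_predictions(config$predictions_csv),
         panel = read_panel(config$panel_csv))
  }
}

config_snapshot <- function(config) {
  cfg <- unclass(config)
  cfg[vapply(cfg, is.null, logical(1))] <- NULL
  cfg
}

#' Baseline experiment: panel of raters vs the machine
#'
#' Computes the per-rater operating points (after completion filtering),
#' their unweighted mean — the human benchmark — and the machine's ROC
#' curve and AUC on the same images.
#'
#' @param config A [run_config()].
#' @return A list of class `baseline_report`: `rater_points` (tibble),
#'   `mean_point` (one-row tibble), `cnn_roc` (`roc_df`), `config`.
#' @export
run_baseline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_inputs(config)
  grid <- threshold_grid(config$grid_size)
  panel <- select_raters(inputs$panel, min_frac = config$min_frac,
                         n_images = nrow(inputs$predictions))
  points <- rater_operating_points(panel, inputs$predictions)
  report <- structure(
    list(
      rater_points = points,
      mean_point = mean_operating_point(points),
      cnn_roc = roc_curve(inputs$predictions, grid),
      config = config_snapshot(config)
    ),
    class = "baseline_report")
  if (!is.null(config$output_dir)) write_baseline(report, config$output_dir)
  report
}

#' Full hybrid experiment bundle
#'
#' Runs the complete analysis: baseline (rater points, mean point, machine
#' ROC), certainty partition at the configured `s`, sublist dissociation
#' report, and the Monte-Carlo substitution ensemble twice — once with the
#' inner (low-certainty) list substituted and once with the outer list.
#' Operating-region comparisons of the inner-substitution curve against
#' the human mean point are included.
#'
#' @param config A [run_config()].
#' @return A list of class `experiment_report`: `baseline`, `partition`,
#'   `sublists`, `hybrid_inner`, `hybrid_outer`, `comparison` (one-row
#'   tibble), `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_inputs(config)
  grid <- threshold_grid(config$grid_size)
  panel <- select_raters(inputs$panel, min_frac = config$min_frac,
                         n_images = nrow(inputs$predictions))
  partition <- sort_and_partition(inputs$predictions, config$s)

  baseline <- run_baseline(run_config(
    preset = config$preset, predictions_csv = config$predictions_csv,
    panel_csv = config$panel_csv, s = config$s,
    iterations = config$iterations, seed = config$seed,
    grid_size = config$grid_size, min_frac = config$min_frac))
  sublists <- evaluate_sublists(inputs$predictions, panel, partition, grid)
  hybrid_inner <- run_hybrid(inputs$predictions, panel, partition$inner,
                             grid, config$iterations, seed = config$seed)
  hybrid_outer <- run_hybrid(inputs$predictions, panel, partition$outer,
                             grid, config$iterations,
                             seed = config$seed + 1L)

  human <- baseline$mean_point
  comparison <- tibble(
    baseline_auc = attr(baseline$cnn_roc, "auc"),
    human_fpr = human$fpr,
    human_tpr = human$tpr,
    inner_tpr_at_human_fpr = tpr_at_fpr(hybrid_inner$mean_curve, human$fpr),
    inner_fpr_at_human_tpr = fpr_at_tpr(hybrid_inner$mean_curve, human$tpr),
    inner_mean_auc = hybrid_inner$mean_auc,
    outer_mean_auc = hybrid_outer$mean_auc
  )

  report <- structure(
    list(baseline = baseline, partition = partition, sublists = sublists,
         hybrid_inner = hybrid_inner, hybrid_outer = hybrid_outer,
         comparison = comparison, config = config_snapshot(config)),
    class = "experiment_report")
  if (!is.null(config$output_dir)) write_experiment(report, config$output_dir)
  report
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf(
    paste0("Baseline: %d raters; human mean point (FPR %.3f, TPR %.3f); ",
           "machine AUC %.3f\n"),
    nrow(x$rater_points), x$mean_point$fpr, x$mean_point$tpr,
    attr(x$cnn_roc, "auc")))
  invisible(x)
}

#' @export
print.experiment_report <- function(x, ...) {
  print(x$baseline)
  print(x$partition)
  cat("Sublist dissociation:\n")
  print(as.data.frame(
    x$sublists[, c("sublist", "n", "cnn_auc", "human_fpr", "human_tpr")]),
    digits = 3, row.names = FALSE)
  cat(sprintf("Inner substitution:  mean AUC %.3f (curve AUC %.3f)\n",
              x$hybrid_inner$mean_auc, x$hybrid_inner$auc_of_mean_curve))
  cat(sprintf("Outer substitution:  mean AUC %.3f (curve AUC %.3f)\n",
              x$hybrid_outer$mean_auc, x$hybrid_outer$auc_of_mean_curve))
  cat(sprintf(
    paste0("At human-mean FPR %.3f the inner-substituted curve reaches ",
           "TPR %.3f (human TPR %.3f);\nat human-mean TPR its FPR is %.3f ",
           "(human FPR %.3f)\n"),
    x$comparison$human_fpr, x$comparison$inner_tpr_at_human_fpr,
    x$comparison$human_tpr, x$comparison$inner_fpr_at_human_tpr,
    x$comparison$human_fpr))
  invisible(x)
}

# ---- report writers -------------------------------------------------------

write_baseline <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$rater_points, file.path(dir, "rater_points.csv"))
  write_roc(report$cnn_roc, csv_path = file.path(dir, "cnn_roc.csv"))
  jsonlite::write_json(
    list(mean_point = as.list(report$mean_point),
         cnn = as.list(glance(report$cnn_roc)),
         config = report$config),
    file.path(dir, "baseline.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

write_experiment <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_baseline(report$baseline, dir)
  readr::write_csv(report$sublists, file.path(dir, "sublists.csv"))
  write_csv_full(tidy(report$hybrid_inner),
                   file.path(dir, "hybrid_inner_curve.csv"))
  write_csv_full(tidy(report$hybrid_outer),
                   file.path(dir, "hybrid_outer_curve.csv"))
  jsonlite::write_json(
    list(partition = as.list(glance(report$partition)),
         comparison = as.list(report$comparison),
         hybrid_inner = as.list(glance(report$hybrid_inner)),
         hybrid_outer = as.list(glance(report$hybrid_outer)),
         config = report$config),
    file.path(dir, "experiment.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Write a partition to JSON
#'
#' Emits `{s, n, i, j, lower, inner, upper, outer}` with 1-based row
#' positions.
#'
#' @param partition A `score_partition`.
#' @param path Output JSON path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "score_partition"))
  jsonlite::write_json(
    partition[c("s", "n", "i", "j", "lower", "inner", "upper", "outer")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(partition)
}
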