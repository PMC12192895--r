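#' Substitute uncertain classifier scores with sampled human calls
#'
#' Builds one substituted prediction vector: positions outside `subset`
#' keep the CNN score bit-exactly; each position in `subset` receives the
#' binary call of one rater drawn uniformly among the raters with an
#' observed response for that image, independently per position. Uses the
#' current RNG state — seed control belongs to the caller (see
#' [run_hybrid()]).
#'
#' @param data A prediction tibble.
#' @param panel A binarized `rater_panel`.
#' @param subset Integer row positions of the images whose scores are
#'   replaced; may be empty.
#' @return A numeric vector of length `nrow(data)`.
#' @export
substitute_scores <- function(data, panel, subset) {
  data <- as_prediction_set(data)
  calls <- panel_calls(panel, data, subset)
  draw_substituted(data$score, calls, subset)
}

# Internal: per-subset-position list of observed calls, validated once so
# the Monte-Carlo loop can skip re-checking.
panel_calls <- function(panel, data, subset) {
  panel <- as_rater_panel(panel)
  subset <- check_subset(subset, nrow(data))
  calls <- split(panel$call, factor(panel$image_id,
                                    levels = data$image_id))[subset]
  uncovered <- lengths(calls) == 0
  if (any(uncovered)) {
    abort(paste0("No rater response for subset image(s): ",
                 paste(utils::head(data$image_id[subset][uncovered], 3),
                       collapse = ", "), "."),
          class = "hybridroc_coverage_error")
  }
  calls
}

check_subset <- function(subset, n) {
  if (length(subset) == 0) return(integer(0))
  if (anyNA(subset) || any(subset != as.integer(subset)) ||
      any(subset < 1 | subset > n) || anyDuplicated(subset)) {
    abort("`subset` must be unique row positions within the data.",
          class = "hybridroc_input_error")
  }
  as.integer(subset)
}

# Internal: one substitution draw given precomputed per-image call lists.
draw_substituted <- function(scores, calls, subset) {
  if (length(subset) == 0) return(scores)
  lens <- lengths(calls)
  picked <- ceiling(runif(length(subset)) * lens)
  flat <- unlist(calls, use.names = FALSE)
  offset <- cumsum(lens) - lens
  scores[subset] <- as.double(flat[offset + picked])
  scores
}

#' Monte-Carlo hybrid substitution ensemble
#'
#' Runs the augmented hybrid procedure: for each of `iterations` trials,
#' replace the scores of the `subset` images with independently sampled
#' human calls, sweep the shared threshold grid to get an ROC curve, and
#' record its AUC. The per-trial curves are stacked (threshold x rate x
#' iteration) and averaged cell-wise over the trial dimension to give the
#' mean curve; `mean_auc` is the arithmetic mean of the per-trial AUCs.
#' The AUC of the averaged curve is also reported separately
#' (`auc_of_mean_curve`); the two summaries answer different questions and
#' are never conflated. A single RNG stream, seeded once, drives all
#' trials in order, so results are fully reproducible from `seed`.
#'
#' @inheritParams substitute_scores
#' @param grid Shared threshold grid; identical curve shapes across trials
#'   are what make cell-wise averaging well defined.
#' @param iterations Number of Monte-Carlo trials (default 1000).
#' @param seed Integer seed for the substitution draws.
#' @return An object of class `hybrid_result`: list with `mean_curve`
#'   (a `roc_df`), `mean_auc`, `auc_of_mean_curve`, `per_iteration_auc`,
#'   `iterations`, `seed`, `subset`.
#' @examples
#' sim <- make_dissociation_fixture(seed = 7)
#' part <- sort_and_partition(sim$predictions, s = 4)
#' hy <- run_hybrid(sim$predictions, sim$panel, part$inner,
#'                  iterations = 50, seed = 7)
#' glance(hy)
#' @export
run_hybrid <- function(data, panel, subset, grid = threshold_grid(),
                       iterations = 1000, seed = NULL) {
  data <- as_prediction_set(data)
  check_grid(grid)
  if (length(iterations) != 1 || is.na(iterations) || iterations < 1) {
    abort("`iterations` must be a positive integer.",
          class = "hybridroc_input_error")
  }
  iterations <- as.integer(iterations)
  subset <- check_subset(subset, nrow(data))
  calls <- panel_calls(panel, data, subset)
  n_pos <- sum(data$truth == 1)
  n_neg <- sum(data$truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both truth classes are required for the hybrid ROC analysis.",
          class = "hybridroc_single_class_error")
  }

  if (length(subset) == 0) {
    # degenerate contract: no substitution, every trial is the baseline
    # curve; report it exactly rather than accumulating round-off
    rates <- roc_rates(data$score, data$truth, grid)
    auc <- auc_from_rates(rates$fpr, rates$tpr)
    res <- list(fpr = rates$fpr, tpr = rates$tpr,
                aucs = rep(auc, iterations))
    mean_curve <- new_roc_df(
      tibble(threshold = grid, fpr = res$fpr, tpr = res$tpr),
      auc = auc, n = nrow(data), n_pos = n_pos, n_neg = n_neg)
    return(structure(
      list(mean_curve = mean_curve, mean_auc = auc,
           auc_of_mean_curve = auc, per_iteration_auc = res$aucs,
           iterations = iterations, seed = seed, subset = subset),
      class = "hybrid_result"))
  }

  run <- function() {
    fpr_sum <- numeric(length(grid))
    tpr_sum <- numeric(length(grid))
    aucs <- numeric(iterations)
    for (it in seq_len(iterations)) {
      scores <- draw_substituted(data$score, calls, subset)
      rates <- roc_rates(scores, data$truth, grid)
      fpr_sum <- fpr_sum + rates$fpr
      tpr_sum <- tpr_sum + rates$tpr
      aucs[it] <- auc_from_rates(rates$fpr, rates$tpr)
    }
    list(fpr = fpr_sum / iterations, tpr = tpr_sum / iterations,
         aucs = aucs)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  mean_curve <- new_roc_df(
    tibble(threshold = grid, fpr = res$fpr, tpr = res$tpr),
    auc = auc_from_rates(res$fpr, res$tpr),
    n = nrow(data), n_pos = n_pos, n_neg = n_neg)
  structure(
    list(
      mean_curve = mean_curve,
      mean_auc = mean(res$aucs),
      auc_of_mean_curve = attr(mean_curve, "auc"),
      per_iteration_auc = res$aucs,
      iterations = iterations,
      seed = seed,
      subset = subset
    ),
    class = "hybrid_result"
  )
}

# Trapezoid over rates already ordered by descending threshold
# (fpr/tpr non-decreasing), avoiding a tibble round trip in the hot loop.
auc_from_rates <- function(fpr, tpr) {
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf(
    paste0("Hybrid substitution ensemble: %d trials, subset of %d image(s)\n",
           "  mean AUC = %.3f, AUC of averaged curve = %.3f\n"),
    x$iterations, length(x$subset), x$mean_auc, x$auc_of_mean_curve))
  invisible(x)
}

#' @export
tidy.hybrid_result <- function(x, ...) {
  as_tibble(x$mean_curve)
}

#' @export
glance.hybrid_result <- function(x, ...) {
  tibble(
    mean_auc = x$mean_auc,
    auc_of_mean_curve = x$auc_of_mean_curve,
    sd_auc = sd(x$per_iteration_auc),
    iterations = x$iterations,
    subset_size = length(x$subset),
    seed = x$seed %||% NA_integer_
  )
}

#' Sublist dissociation report
#'
#' Evaluates the machine and the human panel separately on the inner
#' (low-certainty) and outer (high-certainty) sublists of a certainty
#' partition: the CNN's ROC AUC restricted to each sublist, and the mean
#' human operating point over the raters' responses restricted to each
#' sublist. A sublist containing a single truth class gets `NA` entries
#' rather than an error.
#'
#' @param data A prediction tibble.
#' @param panel A binarized `rater_panel`.
#' @param partition A `score_partition` from [sort_and_partition()].
#' @param grid Threshold grid for the sublist ROC curves.
#' @return A tibble with one row per sublist (`inner`, `outer`): `n`,
#'   `n_pos`, `n_neg`, `cnn_auc`, `human_fpr`, `human_tpr`, `n_raters`.
#' @export
evaluate_sublists <- function(data, panel, partition,
                              grid = threshold_grid()) {
  data <- as_prediction_set(data)
  panel <- as_rater_panel(panel)
  stopifnot(inherits(partition, "score_partition"))
  purrr::map_dfr(c(inner = "inner", outer = "outer"), function(which) {
    idx <- partition[[which]]
    sub <- subset_predictions(data, idx)
    n_pos <- sum(sub$truth == 1)
    n_neg <- sum(sub$truth == 0)
    auc <- if (n_pos > 0 && n_neg > 0) {
      attr(roc_curve(sub, grid), "auc")
    } else {
      NA_real_
    }
    sub_panel <- panel[panel$image_id %in% sub$image_id, ]
    human <- tryCatch({
      pts <- rater_operating_points(sub_panel, sub)
      mean_operating_point(pts)
    }, error = function(e) tibble(fpr = NA_real_, tpr = NA_real_,
                                  n_fpr = 0L, n_tpr = 0L))
    tibble(sublist = which, n = nrow(sub), n_pos = n_pos, n_neg = n_neg,
           cnn_auc = auc, human_fpr = human$fpr, human_tpr = human$tpr,
           n_raters = max(human$n_fpr, human$n_tpr))
  })
}
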