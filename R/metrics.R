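#' Classification accuracy
#'
#' Fraction of items whose predicted binary label matches the ground truth,
#' \eqn{\frac{1}{n}\sum_i I(y_i = \hat y_i)}.
#'
#' @param truth,predicted Equal-length binary (0/1) vectors.
#' @return A single number in \[0, 1\].
#' @examples
#' accuracy(c(1, 0, 1, 0), c(1, 1, 1, 0))
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) == 0) {
    abort("`truth` must be non-empty.", class = "hybridroc_input_error")
  }
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.",
          class = "hybridroc_input_error")
  }
  check_binary(truth, "truth")
  check_binary(predicted, "predicted")
  mean(truth == predicted)
}

#' Confusion counts and operating point of a binary classifier
#'
#' A non-scored classifier (for example a human rater) is summarised by a
#' single operating point: its false positive rate plotted against its true
#' positive rate. Rates with a zero denominator (a class absent from
#' `truth`) are reported as `NA`, never silently as 0, because single-class
#' subsets do occur in sublist analyses.
#'
#' @inheritParams accuracy
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`, `tpr`,
#'   `fpr`.
#' @examples
#' operating_point(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0))
#' @export
operating_point <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.",
          class = "hybridroc_input_error")
  }
  check_binary(truth, "truth")
  check_binary(predicted, "predicted")
  tp <- sum(truth == 1 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  fp <- sum(truth == 0 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_
  )
}

#' Decision-threshold grid for ROC sweeps
#'
#' Thresholds are strictly decreasing. The first value is a sentinel above
#' every representable score, forcing zero predicted positives (ROC point
#' (0, 0)); the last is 0, at which every item is predicted positive under
#' the `score >= t` rule (ROC point (1, 1)). A fixed shared grid makes
#' curves from different runs cell-alignable, which the Monte-Carlo curve
#' averaging requires.
#'
#' @param size Number of evenly spaced thresholds from 1 down to 0
#'   (default 201, i.e. steps of 0.005); the sentinel is prepended.
#' @param sentinel Value above the maximum score (default 1.01).
#' @return A strictly decreasing numeric vector of length `size + 1`.
#' @export
threshold_grid <- function(size = 201, sentinel = 1.01) {
  if (size < 1) abort("`size` must be >= 1.", class = "hybridroc_input_error")
  if (sentinel <= 1) {
    abort("`sentinel` must exceed 1.", class = "hybridroc_input_error")
  }
  c(sentinel, seq(1, 0, length.out = size))
}

# Internal: validate a threshold grid per its contract.
check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2 || any(diff(grid) >= 0) ||
      grid[1] <= 1 || grid[length(grid)] > 0) {
    abort(paste("Threshold grid must be strictly decreasing, start above 1",
                "and end at or below 0."),
          class = "hybridroc_input_error")
  }
  invisible(grid)
}

# Internal vectorised ROC sweep. Returns list(fpr, tpr) over `grid`.
# Predict positive iff score >= t; counts via findInterval on sorted scores.
roc_rates <- function(scores, truth, grid) {
  pos <- sort(scores[truth == 1])
  neg <- sort(scores[truth == 0])
  list(
    fpr = (length(neg) - findInterval(grid, neg, left.open = TRUE)) /
      length(neg),
    tpr = (length(pos) - findInterval(grid, pos, left.open = TRUE)) /
      length(pos)
  )
}

#' Empirical ROC curve on an explicit threshold grid
#'
#' For each threshold `t` the item is predicted malignant iff
#' `score >= t`; the false and true positive rates at each threshold trace
#' the curve. The AUC is the trapezoidal area under the curve ordered by
#' FPR. With a grid containing every distinct score value this equals the
#' Mann-Whitney statistic (probability that a random malignant image
#' outscores a random benign one, ties counted half).
#'
#' @param data A prediction tibble (see [as_prediction_set()]).
#' @param grid A threshold grid (see [threshold_grid()]).
#' @return A tibble of class `roc_df` with columns `threshold`, `fpr`,
#'   `tpr`, and attributes `auc`, `n`, `n_pos`, `n_neg`.
#' @examples
#' preds <- as_prediction_set(
#'   data.frame(image_id = 1:4, score = c(0.1, 0.4, 0.35, 0.8),
#'              truth = c(0, 0, 1, 1)))
#' glance(roc_curve(preds))
#' @export
roc_curve <- function(data, grid = threshold_grid()) {
  data <- as_prediction_set(data)
  check_grid(grid)
  n_pos <- sum(data$truth == 1)
  n_neg <- sum(data$truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    missing_class <- if (n_pos == 0) "malignant (truth = 1)" else
      "benign (truth = 0)"
    abort(paste0("ROC curve undefined: no ", missing_class,
                 " images in the prediction set."),
          class = "hybridroc_single_class_error")
  }
  rates <- roc_rates(data$score, data$truth, grid)
  new_roc_df(tibble(threshold = grid, fpr = rates$fpr, tpr = rates$tpr),
             auc = auc_trapezoid(tibble(fpr = rates$fpr, tpr = rates$tpr)),
             n = nrow(data), n_pos = n_pos, n_neg = n_neg)
}

new_roc_df <- function(points, auc, n, n_pos, n_neg) {
  structure(points,
            auc = auc, n = n, n_pos = n_pos, n_neg = n_neg,
            class = c("roc_df", class(points)))
}

#' Trapezoidal area under a set of ROC points
#'
#' Points are sorted by FPR (stable, so TPR order at tied FPR is kept) and
#' integrated by the trapezoidal rule. Duplicate points contribute zero
#' width and do not change the area.
#'
#' @param points A data frame with columns `fpr` and `tpr`, containing the
#'   endpoints (0, 0) and (1, 1).
#' @return The area, a single number.
#' @examples
#' auc_trapezoid(data.frame(fpr = c(0, 0.5, 0.5, 1),
#'                          tpr = c(0, 0.5, 0.9, 1)))
#' @export
auc_trapezoid <- function(points) {
  if (!is.data.frame(points) || !all(c("fpr", "tpr") %in% names(points))) {
    abort("`points` must be a data frame with `fpr` and `tpr` columns.",
          class = "hybridroc_input_error")
  }
  if (nrow(unique(points[, c("fpr", "tpr")])) < 2) {
    abort("At least two distinct ROC points are required.",
          class = "hybridroc_input_error")
  }
  ord <- order(points$fpr)
  x <- points$fpr[ord]
  y <- points$tpr[ord]
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Interpolated TPR at a target FPR (and vice versa)
#'
#' Reads an operating-region value off a (possibly averaged) ROC curve by
#' linear interpolation. At a tied x-value `tpr_at_fpr()` takes the highest
#' TPR attained and `fpr_at_tpr()` the lowest FPR, i.e. the favourable face
#' of a vertical or horizontal curve segment.
#'
#' @param curve A data frame with `fpr` and `tpr` columns (e.g. a `roc_df`
#'   or the mean curve of a hybrid result).
#' @param fpr,tpr The target rate, in \[0, 1\].
#' @return A single interpolated rate.
#' @export
tpr_at_fpr <- function(curve, fpr) {
  approx(curve$fpr, curve$tpr, xout = fpr, ties = max, rule = 2)$y
}

#' @rdname tpr_at_fpr
#' @export
fpr_at_tpr <- function(curve, tpr) {
  approx(curve$tpr, curve$fpr, xout = tpr, ties = min, rule = 2)$y
}

#' @export
glance.roc_df <- function(x, ...) {
  tibble(
    auc = attr(x, "auc"),
    n = attr(x, "n"),
    n_pos = attr(x, "n_pos"),
    n_neg = attr(x, "n_neg"),
    grid_size = nrow(x)
  )
}

#' @export
print.roc_df <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, n = %d (%d+/%d-), AUC = %.3f\n",
              nrow(x), attr(x, "n"), attr(x, "n_pos"), attr(x, "n_neg"),
              attr(x, "auc")))
  NextMethod()
}

#' Write an ROC curve and its summary to disk
#'
#' The curve goes to a `threshold,fpr,tpr` CSV at full precision; the
#' summary (`auc`, `n`, `n_pos`, `n_neg`, `grid_size`) to a JSON file.
#'
#' @param curve A `roc_df` from [roc_curve()].
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return `curve`, invisibly.
#' @export
write_roc <- function(curve, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    write_csv_full(as_tibble(curve), csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(glance(curve)), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(curve)
}
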