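#' Certainty-based partition of classifier scores
#'
#' Sorts the score array ascending (stably, so ties keep input order) and
#' cuts it at ranks `i = floor(n/s)` and `j = floor((s-1) n / s)` into three
#' lists: `lower` (ranks 1..i, scores nearest 0), `inner` (ranks i+1..j,
#' scores nearest 0.5 — the low-certainty items), and `upper` (ranks
#' j+1..n, scores nearest 1). `outer` is the concatenation of `lower` and
#' `upper`: the high-certainty items, whose scores sit near 0 or 1. All
#' lists are stored as positions into the original (unsorted) prediction
#' table, preserving the rank-to-origin mapping the hybrid substitution
#' consumes. With `s = 4` the inner and outer lists have equal size when
#' `n` is a multiple of 4 (e.g. 75 and 75 at n = 150).
#'
#' @param data A prediction tibble (see [as_prediction_set()]).
#' @param s Integer partition parameter, strictly greater than 2; `n/s` of
#'   the items fall in each of `lower` and `upper` (up to flooring).
#' @return An object of class `score_partition`: a list with elements `s`,
#'   `n`, `i`, `j`, `order` (permutation: sorted rank -> original row),
#'   and the index vectors `lower`, `inner`, `upper`, `outer`.
#' @examples
#' preds <- as_prediction_set(data.frame(
#'   image_id = 1:10,
#'   score = c(0.9, 0.1, 0.5, 0.4, 0.6, 0.05, 0.95, 0.45, 0.55, 0.2),
#'   truth = rep(c(0, 1), 5)))
#' sort_and_partition(preds, s = 5)
#' @export
sort_and_partition <- function(data, s) {
  data <- as_prediction_set(data)
  if (length(s) != 1 || is.na(s) || s != as.integer(s) || s <= 2) {
    abort("`s` must be a single integer greater than 2.",
          class = "hybridroc_constraint_error")
  }
  s <- as.integer(s)
  n <- nrow(data)
  if (n < s) {
    abort(sprintf("Need at least s = %d images to partition; got %d.", s, n),
          class = "hybridroc_degenerate_error")
  }
  i <- floor(n / s)
  j <- floor((s - 1) * n / s)
  ord <- order(data$score) # stable: ties broken by original position
  structure(
    list(
      s = s, n = n, i = i, j = j, order = ord,
      lower = ord[seq_len(i)],
      inner = ord[seq.int(i + 1, j)],
      upper = ord[seq.int(j + 1, n)],
      outer = c(ord[seq_len(i)], ord[seq.int(j + 1, n)])
    ),
    class = "score_partition"
  )
}

#' @export
print.score_partition <- function(x, ...) {
  cat(sprintf(
    "Certainty partition: n = %d, s = %d (cuts i = %d, j = %d)\n",
    x$n, x$s, x$i, x$j))
  cat(sprintf("  lower %d | inner %d | upper %d  (outer = %d)\n",
              length(x$lower), length(x$inner), length(x$upper),
              length(x$outer)))
  invisible(x)
}

#' @export
tidy.score_partition <- function(x, ...) {
  membership <- character(x$n)
  membership[x$lower] <- "lower"
  membership[x$inner] <- "inner"
  membership[x$upper] <- "upper"
  tibble(
    row = seq_len(x$n),
    rank = order(x$order), # rank of each original row in the sorted array
    list = membership,
    outer = membership != "inner"
  )
}

#' @export
glance.score_partition <- function(x, ...) {
  tibble(s = x$s, n = x$n, i = x$i, j = x$j,
         n_lower = length(x$lower), n_inner = length(x$inner),
         n_upper = length(x$upper), n_outer = length(x$outer))
}

#' Restrict a prediction set to a list of rows
#'
#' Extracts the listed images (by original row position) preserving their
#' original relative order, e.g. to evaluate a classifier on the inner or
#' outer sublist of a [sort_and_partition()] result.
#'
#' @param data A prediction tibble.
#' @param indices Unique, in-range row positions.
#' @return A prediction tibble with `length(indices)` rows.
#' @export
subset_predictions <- function(data, indices) {
  data <- as_prediction_set(data)
  if (length(indices) == 0) {
    abort("`indices` is empty; an empty prediction set is not valid.",
          class = "hybridroc_input_error")
  }
  if (anyNA(indices) || any(indices != as.integer(indices)) ||
      any(indices < 1 | indices > nrow(data))) {
    abort("`indices` must be integer row positions within the data.",
          class = "hybridroc_input_error")
  }
  if (anyDuplicated(indices)) {
    abort("`indices` must not contain duplicates.",
          class = "hybridroc_input_error")
  }
  data[sort(as.integer(indices)), ]
}
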