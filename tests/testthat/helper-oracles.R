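# Independent oracles and small fixture builders used across the suite.

# Mann-Whitney AUC by exhaustive pair enumeration: P(score+ > score-) with
# ties counted one half. Independent of the trapezoidal ROC path.
mann_whitney_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# A grid that hits every observed score exactly, plus the contract's
# sentinels, so the swept ROC curve has a vertex at each score value and
# the trapezoid equals the Mann-Whitney statistic.
grid_for_scores <- function(scores) {
  c(1.01, sort(unique(c(scores, 0)), decreasing = TRUE))
}

# Minimal prediction table.
pred_set <- function(scores, truth, ids = seq_along(scores)) {
  as_prediction_set(
    tibble::tibble(image_id = as.character(ids), score = scores,
                   truth = truth))
}

# Long panel from a raters x images call matrix (NA = missing).
panel_from_matrix <- function(calls, image_ids = NULL) {
  image_ids <- image_ids %||% as.character(seq_len(ncol(calls)))
  long <- tibble::tibble(
    rater_id = rep(sprintf("r%02d", seq_len(nrow(calls))), ncol(calls)),
    image_id = rep(image_ids, each = nrow(calls)),
    call = as.integer(as.vector(calls))
  )
  as_rater_panel(long[!is.na(long$call), ])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
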