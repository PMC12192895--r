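#' Validate a prediction table
#'
#' A prediction set is the basic evaluation container: one row per image with
#' a continuous malignancy score from a classifier and a histopathology
#' ground-truth label. All downstream analyses (ROC curves, certainty
#' partition, hybrid substitution) consume this table.
#'
#' @param data A data frame with columns `image_id` (unique identifiers),
#'   `score` (real in \[0, 1\]) and `truth` (0 = benign, 1 = malignant).
#' @return A tibble with the three validated columns, in input order.
#' @examples
#' as_prediction_set(data.frame(image_id = c("a", "b"),
#'                              score = c(0.9, 0.2), truth = c(1, 0)))
#' @export
as_prediction_set <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "hybridroc_input_error")
  }
  missing_cols <- setdiff(c("image_id", "score", "truth"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "hybridroc_input_error")
  }
  out <- as_tibble(data)[, c("image_id", "score", "truth")]
  if (nrow(out) < 1) {
    abort("Prediction set must contain at least one image.",
          class = "hybridroc_input_error")
  }
  if (anyDuplicated(out$image_id)) {
    abort("`image_id` values must be unique.",
          class = "hybridroc_input_error")
  }
  if (!is.numeric(out$score) || anyNA(out$score) ||
      any(out$score < 0 | out$score > 1)) {
    abort("`score` must be numeric in [0, 1] with no missing values.",
          class = "hybridroc_input_error")
  }
  check_binary(out$truth, "truth")
  out$score <- as.double(out$score)
  out$truth <- as.integer(out$truth)
  out
}

#' Read or write a prediction CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header
#' `image_id,score,truth`. Scores are written at full precision so a
#' write-then-read round trip is exact.
#'
#' @param path Path to the CSV file.
#' @return `read_predictions()` returns a validated prediction tibble;
#'   `write_predictions()` returns `data` invisibly.
#' @export
read_predictions <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    score = readr::col_character(), # exact strtod conversion below
    truth = readr::col_integer()
  ))
  problems <- readr::problems(data)
  if (nrow(problems) > 0) {
    abort(paste0("Malformed prediction CSV at row ", problems$row[1],
                 ": ", problems$expected[1], " expected."),
          class = "hybridroc_parse_error")
  }
  score <- suppressWarnings(as.numeric(data$score))
  bad <- which(is.na(score) & !is.na(data$score))
  if (length(bad) > 0) {
    abort(paste0("Malformed prediction CSV at row ", bad[1],
                 ": numeric score expected."),
          class = "hybridroc_parse_error")
  }
  data$score <- score
  as_prediction_set(data)
}

#' @rdname read_predictions
#' @param data A prediction tibble (see [as_prediction_set()]).
#' @export
write_predictions <- function(data, path) {
  data <- as_prediction_set(data)
  write_csv_full(data, path)
  invisible(data)
}

# Internal: CSV writer that renders double columns with 17 significant
# digits so a write-then-read round trip is bit-exact.
write_csv_full <- function(data, path) {
  out <- data
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  readr::write_csv(out, path)
  invisible(data)
}

# Internal: assert a vector is strictly 0/1 with no NA.
check_binary <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    abort(paste0("`", name, "` must contain only 0 or 1, no missing values."),
          class = "hybridroc_input_error")
  }
  invisible(x)
}
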