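#' Three-point checklist binarization
#'
#' Dermoscopic readers score each lesion on three binary criteria:
#' asymmetry (of colour/structure), atypical pigment network, and
#' blue-white structures. A lesion is called malignant when two or more
#' criteria are present.
#'
#' @param asymmetry,network,bluewhite Equal-length 0/1 vectors, one element
#'   per response.
#' @return An integer 0/1 vector: 1 iff at least two criteria are present.
#' @examples
#' checklist_to_label(1, 1, 0) # malignant
#' checklist_to_label(1, 0, 0) # benign
#' @export
checklist_to_label <- function(asymmetry, network, bluewhite) {
  if (length(asymmetry) != length(network) ||
      length(network) != length(bluewhite)) {
    abort("The three criterion vectors must have equal length.",
          class = "hybridroc_input_error")
  }
  check_binary(asymmetry, "asymmetry")
  check_binary(network, "network")
  check_binary(bluewhite, "bluewhite")
  as.integer(asymmetry + network + bluewhite >= 2)
}

#' Validate a long-format rater panel
#'
#' A rater panel records one row per (rater, image) response. Two input
#' layouts are accepted: a binarized `call` column, or the three checklist
#' criterion columns `asymmetry`, `network`, `bluewhite` (binarized on the
#' fly via [checklist_to_label()]). A missing response is either an absent
#' row or an `NA` call/criterion; missing responses are dropped so the
#' validated panel holds observed calls only.
#'
#' @param data A data frame with columns `rater_id`, `image_id` and either
#'   `call` or the three criterion columns.
#' @return A tibble of class `rater_panel` with columns `rater_id`,
#'   `image_id`, `call` (0/1 integer), one row per observed response.
#' @export
as_rater_panel <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "hybridroc_input_error")
  }
  if (!all(c("rater_id", "image_id") %in% names(data))) {
    abort("Panel needs `rater_id` and `image_id` columns.",
          class = "hybridroc_input_error")
  }
  out <- as_tibble(data)
  criteria <- c("asymmetry", "network", "bluewhite")
  if ("call" %in% names(out)) {
    out <- out[, c("rater_id", "image_id", "call")]
  } else if (all(criteria %in% names(out))) {
    complete <- !is.na(out$asymmetry) & !is.na(out$network) &
      !is.na(out$bluewhite)
    out <- out[complete, ]
    out$call <- checklist_to_label(out$asymmetry, out$network, out$bluewhite)
    out <- out[, c("rater_id", "image_id", "call")]
  } else {
    abort(paste("Panel needs either a `call` column or the criterion",
                "columns `asymmetry`, `network`, `bluewhite`."),
          class = "hybridroc_input_error")
  }
  out <- out[!is.na(out$call), ]
  if (anyDuplicated(out[, c("rater_id", "image_id")])) {
    abort("Each (rater_id, image_id) pair may appear at most once.",
          class = "hybridroc_input_error")
  }
  check_binary(out$call, "call")
  out$call <- as.integer(out$call)
  class(out) <- unique(c("rater_panel", class(out)))
  out
}

#' Read a rater-panel CSV
#'
#' Long format, one row per response: either `rater_id,image_id,call` or
#' `rater_id,image_id,asymmetry,network,bluewhite`. A blank cell marks a
#' missing response.
#'
#' @param path Path to the CSV file.
#' @return A validated `rater_panel` tibble.
#' @export
read_panel <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    rater_id = readr::col_character(),
    image_id = readr::col_character(),
    .default = readr::col_integer()
  ))
  problems <- readr::problems(data)
  if (nrow(problems) > 0) {
    abort(paste0("Malformed panel CSV at row ", problems$row[1], "."),
          class = "hybridroc_parse_error")
  }
  as_rater_panel(data)
}

#' @rdname read_panel
#' @param panel A `rater_panel` tibble.
#' @export
write_panel <- function(panel, path) {
  panel <- as_rater_panel(panel)
  readr::write_csv(as_tibble(panel), path)
  invisible(panel)
}

#' Per-rater completion counts
#'
#' @param panel A `rater_panel` tibble.
#' @return A tibble `rater_id`, `n_completed` (observed responses).
#' @export
rater_completion <- function(panel) {
  panel <- as_rater_panel(panel)
  dplyr::count(as_tibble(panel), .data$rater_id, name = "n_completed")
}

#' Filter raters by completion
#'
#' Reader studies commonly admit only raters who assessed most of the
#' image set (the reference design keeps raters who completed at least
#' 126 of 150 images, i.e. 84%). Retains exactly the raters whose number
#' of observed responses meets the threshold; responses of retained raters
#' are untouched.
#'
#' @param panel A `rater_panel` tibble.
#' @param min_completed Absolute completion threshold (count). When `NULL`
#'   (default) it is derived as `ceiling(min_frac * n_images)`.
#' @param min_frac Fractional threshold, default 0.84.
#' @param n_images Total images in the study; defaults to the number of
#'   distinct images appearing in the panel.
#' @return The filtered `rater_panel` (possibly with zero raters).
#' @export
select_raters <- function(panel, min_completed = NULL, min_frac = 0.84,
                          n_images = NULL) {
  panel <- as_rater_panel(panel)
  if (is.null(min_completed)) {
    n_images <- n_images %||% dplyr::n_distinct(panel$image_id)
    min_completed <- ceiling(min_frac * n_images)
  }
  if (min_completed < 0) {
    abort("`min_completed` must be >= 0.", class = "hybridroc_input_error")
  }
  keep <- rater_completion(panel)
  keep <- keep$rater_id[keep$n_completed >= min_completed]
  out <- panel[panel$rater_id %in% keep, ]
  class(out) <- unique(c("rater_panel", class(out)))
  out
}

#' Operating point of every rater
#'
#' Each rater is scored only over the images they answered; undefined rates
#' (a rater who saw a single truth class) are `NA`, not 0.
#'
#' @param panel A `rater_panel` tibble with binarized calls.
#' @param data A prediction tibble carrying the ground truth per `image_id`
#'   (scores are ignored).
#' @return A tibble with one row per rater: `rater_id`, `n_answered`,
#'   `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`.
#' @export
rater_operating_points <- function(panel, data) {
  panel <- as_rater_panel(panel)
  data <- as_prediction_set(data)
  unknown <- setdiff(panel$image_id, data$image_id)
  if (length(unknown) > 0) {
    abort(paste0("Panel references image(s) absent from the prediction set: ",
                 paste(utils::head(unknown, 3), collapse = ", "), "."),
          class = "hybridroc_input_error")
  }
  joined <- dplyr::left_join(as_tibble(panel),
                             data[, c("image_id", "truth")], by = "image_id")
  joined |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::summarise(
      n_answered = dplyr::n(),
      operating_point(.data$truth, .data$call),
      .groups = "drop"
    )
}

#' Mean human operating point
#'
#' The human benchmark is the unweighted arithmetic mean of the per-rater
#' FPR and TPR — the mean performance level of individuals, not a pooled
#' ensemble. Raters with an undefined rate are skipped for that rate and
#' the count of skips is reported.
#'
#' @param points A tibble of operating points (needs `fpr`, `tpr` columns),
#'   e.g. from [rater_operating_points()].
#' @return A one-row tibble: `fpr`, `tpr`, `n_fpr`, `n_tpr` (raters used
#'   per rate), `n_skipped_fpr`, `n_skipped_tpr`.
#' @export
mean_operating_point <- function(points) {
  if (!is.data.frame(points) || !all(c("fpr", "tpr") %in% names(points)) ||
      nrow(points) == 0) {
    abort("`points` must be a non-empty data frame with `fpr` and `tpr`.",
          class = "hybridroc_input_error")
  }
  ok_f <- !is.na(points$fpr)
  ok_t <- !is.na(points$tpr)
  if (!any(ok_f) || !any(ok_t)) {
    abort("All rates are undefined; no mean operating point exists.",
          class = "hybridroc_degenerate_error")
  }
  tibble(
    fpr = mean(points$fpr[ok_f]),
    tpr = mean(points$tpr[ok_t]),
    n_fpr = sum(ok_f), n_tpr = sum(ok_t),
    n_skipped_fpr = sum(!ok_f), n_skipped_tpr = sum(!ok_t)
  )
}
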