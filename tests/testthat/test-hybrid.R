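test_that("empty subset leaves scores and ensemble bit-exact at baseline", {
  preds <- pred_set(c(0.13, 0.87, 0.44, 0.71), c(0, 1, 0, 1))
  panel <- panel_from_matrix(rbind(c(0L, 1L, 0L, 1L)))
  expect_identical(substitute_scores(preds, panel, integer(0)), preds$score)

  base <- roc_curve(preds)
  hy <- run_hybrid(preds, panel, integer(0), iterations = 7, seed = 99)
  expect_identical(hy$mean_curve$fpr, base$fpr)
  expect_identical(hy$mean_curve$tpr, base$tpr)
  expect_identical(hy$mean_auc, attr(base, "auc"))
  expect_identical(unique(hy$per_iteration_auc), attr(base, "auc"))
})

test_that("full substitution against a single rater returns that rater", {
  preds <- pred_set(c(0.2, 0.6, 0.9), c(0, 1, 1))
  panel <- panel_from_matrix(rbind(c(1L, 0L, 1L)))
  out <- withr::with_seed(1, substitute_scores(preds, panel, 1:3))
  expect_equal(out, c(1, 0, 1))
})

test_that("substitution samples responding raters uniformly", {
  preds <- pred_set(c(0.5, 0.9), c(1, 0))
  panel <- panel_from_matrix(rbind(c(0L, 1L), c(1L, 1L)))
  draws <- withr::with_seed(123, {
    replicate(10000, substitute_scores(preds, panel, 1)[1])
  })
  # mean of a fair 0/1 draw over 10,000 trials: 0.5 +- 3 * 0.005
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(10000))
})

test_that("a subset image with no responses raises a coverage error", {
  preds <- pred_set(c(0.5, 0.9), c(1, 0), ids = c("a", "b"))
  panel <- panel_from_matrix(rbind(c(1L, NA)), image_ids = c("a", "b"))
  expect_error(substitute_scores(preds, panel, 2), "b",
               class = "hybridroc_coverage_error")
  expect_error(run_hybrid(preds, panel, 1:2, iterations = 2, seed = 1),
               class = "hybridroc_coverage_error")
})

test_that("hybrid runs are reproducible and internally consistent", {
  sim <- make_dissociation_fixture(seed = 4)
  part <- sort_and_partition(sim$predictions, 4)
  h1 <- run_hybrid(sim$predictions, sim$panel, part$inner,
                   iterations = 25, seed = 17)
  h2 <- run_hybrid(sim$predictions, sim$panel, part$inner,
                   iterations = 25, seed = 17)
  expect_identical(h1, h2)
  expect_length(h1$per_iteration_auc, 25)
  expect_equal(h1$mean_auc, mean(h1$per_iteration_auc), tolerance = 1e-13)
  # averaged curve keeps all ROC-curve invariants
  mc <- h1$mean_curve
  expect_equal(c(mc$fpr[1], mc$tpr[1]), c(0, 0))
  expect_equal(c(mc$fpr[nrow(mc)], mc$tpr[nrow(mc)]), c(1, 1))
  expect_true(all(diff(mc$fpr) >= 0) && all(diff(mc$tpr) >= 0))
  # the two AUC summaries are distinct fields, both in [0, 1]
  expect_true(h1$mean_auc >= 0 && h1$mean_auc <= 1)
  expect_true(h1$auc_of_mean_curve >= 0 && h1$auc_of_mean_curve <= 1)
  expect_named(glance(h1),
               c("mean_auc", "auc_of_mean_curve", "sd_auc", "iterations",
                 "subset_size", "seed"))
})

test_that("two-outcome substitution converges to the enumerated mixture", {
  # one substitutable image, two raters disagreeing there: exactly two
  # equiprobable deterministic outcomes, so every expectation has a
  # closed form by enumeration
  preds <- pred_set(c(0.45, 0.85, 0.15, 0.65), c(1, 1, 0, 0))
  panel <- panel_from_matrix(rbind(c(0L, 1L, 0L, 0L),
                                   c(1L, 1L, 0L, 0L)))
  grid <- threshold_grid(21)
  outcome <- function(call1) {
    scores <- preds$score
    scores[1] <- call1
    roc_curve(pred_set(scores, preds$truth), grid)
  }
  c0 <- outcome(0)
  c1 <- outcome(1)
  iters <- 10000
  hy <- run_hybrid(preds, panel, 1, grid, iterations = iters, seed = 77)

  # cell-wise: mean = (c0 + c1)/2, SE = |c1 - c0| * 0.5 / sqrt(iters)
  for (col in c("fpr", "tpr")) {
    expected <- (c0[[col]] + c1[[col]]) / 2
    se <- abs(c1[[col]] - c0[[col]]) * 0.5 / sqrt(iters)
    expect_true(all(abs(hy$mean_curve[[col]] - expected) <= 3 * se + 1e-12))
  }
  auc_expected <- (attr(c0, "auc") + attr(c1, "auc")) / 2
  auc_se <- abs(attr(c1, "auc") - attr(c0, "auc")) * 0.5 / sqrt(iters)
  expect_lt(abs(hy$mean_auc - auc_expected), 3 * auc_se)
})

test_that("sublist evaluation accounts for every image exactly once", {
  sim <- make_dissociation_fixture(seed = 9)
  part <- sort_and_partition(sim$predictions, 4)
  rep <- evaluate_sublists(sim$predictions, sim$panel, part)
  expect_equal(sort(rep$sublist), c("inner", "outer"))
  expect_equal(sum(rep$n), nrow(sim$predictions))
  expect_equal(sum(rep$n_pos) + sum(rep$n_neg), nrow(sim$predictions))
  # dissociation: machine weakest on the uncertain inner list
  expect_lt(rep$cnn_auc[rep$sublist == "inner"],
            rep$cnn_auc[rep$sublist == "outer"])
})

test_that("single-class sublists yield NA entries, not errors", {
  # n = 8, s = 4: lower 2, inner 4, upper 2; inner ranks all benign
  scores <- c(0.01, 0.02, 0.30, 0.35, 0.40, 0.45, 0.98, 0.99)
  truth <- c(0, 1, 0, 0, 0, 0, 1, 1)
  preds <- pred_set(scores, truth)
  panel <- panel_from_matrix(rbind(as.integer(truth)))
  part <- sort_and_partition(preds, 4)
  expect_true(all(preds$truth[part$inner] == 0))
  rep <- evaluate_sublists(preds, panel, part)
  inner <- rep[rep$sublist == "inner", ]
  outer <- rep[rep$sublist == "outer", ]
  expect_true(is.na(inner$cnn_auc)) # undefined, marked not raised
  expect_true(is.na(inner$human_tpr))
  expect_false(is.na(outer$cnn_auc)) # both tails mix classes
})
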