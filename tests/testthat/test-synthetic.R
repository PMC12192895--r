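test_that("ground-truth generation matches its incidence", {
  withr::with_seed(101, {
    y <- gen_truth(10000, 0.297)
    se <- sqrt(0.297 * 0.703 / 10000)
    expect_lt(abs(mean(y) - 0.297), 3 * se)
    expect_equal(gen_truth(100, 1e-9), rep(0L, 100))
  })
  expect_identical(withr::with_seed(3, gen_truth(50, 0.3)),
                   withr::with_seed(3, gen_truth(50, 0.3)))
  expect_error(gen_truth(10, 0), class = "hybridroc_input_error")
  expect_error(gen_truth(10, 1), class = "hybridroc_input_error")
})

test_that("score generator spans the uninformative and sharp limits", {
  n <- 10000
  withr::with_seed(7, {
    y <- rbinom(n, 1, 0.4)
    # fully difficult: scores carry no class signal
    s_flat <- gen_cnn_scores(y, rep(1, n), kappa = 12)
    expect_lt(abs(mann_whitney_auc(s_flat, y) - 0.5), 0.03)
    # trivial items at extreme concentration: scores hug the targets
    s_sharp <- gen_cnn_scores(y, rep(0, n), kappa = 10000)
    expect_true(all(abs(s_sharp - ifelse(y == 1, 0.98, 0.02)) < 0.05))
    expect_equal(mann_whitney_auc(s_sharp, y), 1.0)
  })
})

test_that("machine-hard items concentrate in the inner list", {
  n <- 2000
  withr::with_seed(19, {
    y <- rbinom(n, 1, 0.3)
    d <- sample(c(0.1, 0.9), n, replace = TRUE)
    s <- gen_cnn_scores(y, d, kappa = 12)
  })
  part <- sort_and_partition(pred_set(s, y), 4)
  frac_hard_inner <- mean(d[part$inner] == 0.9)
  frac_hard_overall <- mean(d == 0.9)
  # with half the items hard, the ceiling of the enrichment ratio is 2
  # (inner holds half the set); mid-0.5 scores sort inward, so the inner
  # list is dominated by hard items
  expect_gte(frac_hard_inner / frac_hard_overall, 1.5)
  expect_gte(frac_hard_inner, 0.75)
})

test_that("raising machine difficulty never helps the classifier", {
  withr::with_seed(29, {
    for (rep in 1:5) {
      n <- 800
      y <- rbinom(n, 1, 0.35)
      d <- runif(n, 0, 0.6)
      seed_pair <- sample.int(1e6, 1)
      a_lo <- mann_whitney_auc(
        withr::with_seed(seed_pair, gen_cnn_scores(y, d, 12)), y)
      a_hi <- mann_whitney_auc(
        withr::with_seed(seed_pair, gen_cnn_scores(y, pmin(d + 0.3, 1), 12)),
        y)
      expect_lte(a_hi, a_lo + 0.02)
    }
  })
})

test_that("panel generator hits the configured rater skill limits", {
  n <- 5000
  cfg_ids <- sprintf("i%04d", seq_len(n))
  withr::with_seed(41, {
    y <- rbinom(n, 1, 0.3)
    perfect <- synthetic_config(n_images = n, n_raters = 4,
                                rater_sensitivity = rep(0.999999, 4),
                                rater_specificity = rep(0.999999, 4),
                                miss_prob = 0, seed = 41)
    panel <- gen_panel(y, rep(0, n), perfect, image_ids = cfg_ids)
  })
  pts <- rater_operating_points(panel, pred_set(runif(n), y, ids = cfg_ids))
  expect_true(all(pts$tpr > 0.999))
  expect_true(all(pts$fpr < 0.001))

  # full difficulty: accuracy collapses to the coin-flip level
  withr::with_seed(43, {
    coin <- synthetic_config(n_images = n, n_raters = 6,
                             rater_sensitivity = c(0.9, 0.99),
                             rater_specificity = c(0.9, 0.99),
                             miss_prob = 0, seed = 43)
    panel2 <- gen_panel(y, rep(1, n), coin, image_ids = cfg_ids)
  })
  truth_lookup <- stats::setNames(y, cfg_ids)
  acc <- tapply(panel2$call == truth_lookup[panel2$image_id],
                panel2$rater_id, mean)
  expect_true(all(abs(acc - 0.5) < 3 * sqrt(0.25 / n)))
})

test_that("every image keeps at least one response under missingness", {
  withr::with_seed(53, {
    y <- rbinom(40, 1, 0.3)
    cfg <- synthetic_config(n_images = 40, n_raters = 3,
                            miss_prob = 0.9, seed = 53)
    panel <- gen_panel(y, rep(0.2, 40), cfg)
  })
  expect_equal(dplyr::n_distinct(panel$image_id), 40)
})

test_that("difficulty copula respects its correlation parameter", {
  withr::with_seed(61, {
    ind <- gen_difficulties(20000, rho = 0)
    pos <- gen_difficulties(20000, rho = 0.8)
  })
  expect_lt(abs(cor(ind$machine, ind$human)), 0.03)
  expect_gt(cor(pos$machine, pos$human), 0.6)
  expect_true(all(ind$machine >= 0 & ind$machine <= 1))
})

test_that("simulation and fixture are deterministic in their seed", {
  s1 <- simulate_study(synthetic_config(n_images = 40, n_raters = 5,
                                        seed = 8))
  s2 <- simulate_study(synthetic_config(n_images = 40, n_raters = 5,
                                        seed = 8))
  expect_identical(s1$predictions, s2$predictions)
  expect_identical(s1$panel, s2$panel)

  f1 <- make_dissociation_fixture(seed = 2)
  f2 <- make_dissociation_fixture(seed = 2)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$panel, f2$panel)
  # write-and-reread both artifacts byte-identically
  d <- withr::local_tempdir()
  write_predictions(f1$predictions, file.path(d, "a.csv"))
  write_predictions(f2$predictions, file.path(d, "b.csv"))
  expect_identical(readLines(file.path(d, "a.csv")),
                   readLines(file.path(d, "b.csv")))
})

test_that("fixture exhibits the documented partition and dissociation", {
  sim <- make_dissociation_fixture(seed = 1)
  expect_equal(nrow(sim$predictions), 150)
  expect_equal(dplyr::n_distinct(sim$panel$rater_id), 69)
  part <- sort_and_partition(sim$predictions, 4)
  expect_length(part$inner, 75)
  expect_length(part$outer, 75)
  # machine-hard-but-human-easy ordering over several regenerations
  for (sd in c(1, 5, 12)) {
    f <- make_dissociation_fixture(seed = sd)
    rep <- evaluate_sublists(f$predictions, f$panel,
                             sort_and_partition(f$predictions, 4))
    expect_lt(rep$cnn_auc[rep$sublist == "inner"],
              rep$cnn_auc[rep$sublist == "outer"])
  }
})

test_that("synthetic_config validates its ranges", {
  expect_error(synthetic_config(incidence = 0), class = "hybridroc_input_error")
  expect_error(synthetic_config(rater_sensitivity = c(0, 1)),
               class = "hybridroc_input_error")
  expect_error(synthetic_config(machine_difficulty = rep(2, 150)),
               class = "hybridroc_input_error")
  expect_error(synthetic_config(kappa = 0))
})
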