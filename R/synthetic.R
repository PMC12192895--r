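#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the generator that emulates the statistical
#' structure of a dermoscopic reader study: histopathology ground truth at
#' a configurable malignancy incidence, CNN scores whose informativeness
#' varies per image ("machine difficulty"), and a multi-rater panel whose
#' per-rater sensitivity/specificity is degraded per image by "human
#' difficulty". Machine and human difficulty are drawn with a configurable
#' correlation `rho`, so images that are hard for the machine can be easy
#' for humans and vice versa — the dissociation the hybrid substitution
#' exploits. Defaults mirror a reference reader study: 150 images at
#' 29.7% incidence read by a 69-rater panel whose mean sensitivity is
#' 0.765 and mean specificity 0.804.
#'
#' @param n_images Number of images (default 150).
#' @param incidence Malignancy prevalence in (0, 1); default 0.297.
#' @param n_raters Panel size (default 69).
#' @param rater_sensitivity,rater_specificity Either a length-2 range from
#'   which per-rater values are drawn uniformly, or a vector of length
#'   `n_raters`.
#' @param kappa Beta concentration of the score noise (> 0, default 12):
#'   larger values give scores tighter around their difficulty-set target.
#' @param machine_difficulty,human_difficulty Either `NULL` (drawn from the
#'   correlated difficulty model, see [gen_difficulties()]) or a vector of
#'   per-image values in \[0, 1\]. 0 = trivial, 1 = indistinguishable from
#'   a coin flip.
#' @param rho Correlation in \[-1, 1\] between machine and human difficulty
#'   when both are drawn (default 0: independent).
#' @param miss_prob Per-response missingness probability in \[0, 1);
#'   default 0.05.
#' @param seed Integer seed; the same config and seed reproduce identical
#'   outputs.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 150,
                             incidence = 0.297,
                             n_raters = 69,
                             rater_sensitivity = c(0.665, 0.865),
                             rater_specificity = c(0.704, 0.904),
                             kappa = 12,
                             machine_difficulty = NULL,
                             human_difficulty = NULL,
                             rho = 0,
                             miss_prob = 0.05,
                             seed = 1L) {
  stopifnot(n_images >= 1, n_raters >= 1, kappa > 0,
            miss_prob >= 0, miss_prob < 1,
            rho >= -1, rho <= 1)
  if (incidence <= 0 || incidence >= 1) {
    abort("`incidence` must lie strictly in (0, 1).",
          class = "hybridroc_input_error")
  }
  check_rate_spec(rater_sensitivity, n_raters, "rater_sensitivity")
  check_rate_spec(rater_specificity, n_raters, "rater_specificity")
  for (d in list(machine_difficulty, human_difficulty)) {
    if (!is.null(d) &&
        (length(d) != n_images || any(d < 0 | d > 1))) {
      abort("Difficulty vectors must have one value in [0, 1] per image.",
            class = "hybridroc_input_error")
    }
  }
  structure(
    list(n_images = as.integer(n_images), incidence = incidence,
         n_raters = as.integer(n_raters),
         rater_sensitivity = rater_sensitivity,
         rater_specificity = rater_specificity,
         kappa = kappa,
         machine_difficulty = machine_difficulty,
         human_difficulty = human_difficulty,
         rho = rho, miss_prob = miss_prob, seed = as.integer(seed)),
    class = "synthetic_config")
}

check_rate_spec <- function(x, n_raters, name) {
  ok <- is.numeric(x) && !anyNA(x) && all(x > 0 & x < 1) &&
    (length(x) == 2 || length(x) == n_raters)
  if (!ok) {
    abort(paste0("`", name, "` must be a (0,1) range of length 2 or one ",
                 "value per rater."),
          class = "hybridroc_input_error")
  }
  invisible(x)
}

# Expand a range-or-vector rate spec to per-rater values (consumes RNG
# only in the range case).
draw_rates <- function(x, n_raters) {
  if (length(x) == n_raters && n_raters != 2) return(x)
  if (length(x) == 2 && n_raters != 2) return(runif(n_raters, x[1], x[2]))
  # ambiguous only when n_raters == 2: treat length-2 input as a range
  runif(n_raters, min(x), max(x))
}

#' Generate ground-truth labels
#'
#' Independent Bernoulli draws at the given malignancy incidence. Uses the
#' current RNG state.
#'
#' @param n Number of images.
#' @param incidence P(malignant) in (0, 1).
#' @return Integer 0/1 vector of length `n`.
#' @export
gen_truth <- function(n, incidence) {
  if (incidence <= 0 || incidence >= 1) {
    abort("`incidence` must lie strictly in (0, 1).",
          class = "hybridroc_input_error")
  }
  rbinom(n, 1L, incidence)
}

#' Generate correlated machine/human difficulty
#'
#' Draws per-image difficulty pairs from a Gaussian copula with
#' correlation `rho`, mapped to uniform marginals on \[0, 1\]. `rho = 0`
#' gives independent difficulties — the regime where some images are
#' machine-hard yet human-easy.
#'
#' @param n Number of images.
#' @param rho Copula correlation in \[-1, 1\].
#' @return A tibble with columns `machine` and `human`, each in \[0, 1\].
#' @export
gen_difficulties <- function(n, rho = 0) {
  stopifnot(rho >= -1, rho <= 1)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  tibble(machine = stats::pnorm(z1), human = stats::pnorm(z2))
}

#' Generate CNN malignancy scores
#'
#' Each image's score is drawn from a Beta distribution whose mean is the
#' difficulty-shrunk target `m = 0.5 + (y - 0.5) * (1 - d)` (clipped to
#' \[0.02, 0.98\]) with concentration `kappa` (shape1 = m * kappa,
#' shape2 = (1 - m) * kappa). At `d = 1` the score is centred on 0.5
#' regardless of the label (uninformative); at `d = 0` with large `kappa`
#' scores collapse onto 0.98 for malignant and 0.02 for benign images.
#' Uses the current RNG state.
#'
#' @param truth 0/1 label vector.
#' @param machine_difficulty Per-image difficulty in \[0, 1\], same length.
#' @param kappa Beta concentration, > 0.
#' @return Numeric score vector in \[0, 1\].
#' @export
gen_cnn_scores <- function(truth, machine_difficulty, kappa = 12) {
  check_binary(truth, "truth")
  if (length(truth) != length(machine_difficulty) ||
      any(machine_difficulty < 0 | machine_difficulty > 1)) {
    abort("`machine_difficulty` must match `truth` in length, values in [0, 1].",
          class = "hybridroc_input_error")
  }
  if (kappa <= 0) {
    abort("`kappa` must be positive.", class = "hybridroc_input_error")
  }
  m <- 0.5 + (truth - 0.5) * (1 - machine_difficulty)
  m <- pmin(pmax(m, 0.02), 0.98)
  rbeta(length(truth), shape1 = m * kappa, shape2 = (1 - m) * kappa)
}

#' Generate a synthetic rater panel
#'
#' Rater `r` calls a malignant image positive with probability
#' `Se_r * (1 - h) + 0.5 * h` and a benign image negative with probability
#' `Sp_r * (1 - h) + 0.5 * h`, where `h` is the image's human difficulty —
#' at `h = 1` every rater is a coin flip regardless of skill. Each
#' response is independently missing with `miss_prob`; an image left with
#' no response at all has its missingness redrawn, so every image is
#' guaranteed at least one observed call. Uses the current RNG state.
#'
#' @param truth 0/1 label vector (one per image).
#' @param human_difficulty Per-image difficulty in \[0, 1\].
#' @param config A `synthetic_config` (supplies rater ranges, panel size,
#'   missingness).
#' @param image_ids Optional image identifiers; default `img_001` style.
#' @return A `rater_panel` tibble of observed responses.
#' @export
gen_panel <- function(truth, human_difficulty, config,
                      image_ids = NULL) {
  check_binary(truth, "truth")
  n <- length(truth)
  stopifnot(length(human_difficulty) == n,
            all(human_difficulty >= 0 & human_difficulty <= 1),
            inherits(config, "synthetic_config"))
  image_ids <- image_ids %||% sprintf("img_%03d", seq_len(n))
  n_raters <- config$n_raters
  se <- draw_rates(config$rater_sensitivity, n_raters)
  sp <- draw_rates(config$rater_specificity, n_raters)

  # n_raters x n matrix of correct-call probabilities
  h <- matrix(human_difficulty, n_raters, n, byrow = TRUE)
  skill <- ifelse(matrix(truth, n_raters, n, byrow = TRUE) == 1, se, sp)
  p_correct <- skill * (1 - h) + 0.5 * h
  correct <- matrix(rbinom(n_raters * n, 1L, p_correct), n_raters, n)
  truth_mat <- matrix(truth, n_raters, n, byrow = TRUE)
  call <- ifelse(correct == 1L, truth_mat, 1L - truth_mat)

  observed <- matrix(runif(n_raters * n) >= config$miss_prob, n_raters, n)
  for (img in which(colSums(observed) == 0)) {
    while (!any(observed[, img])) {
      observed[, img] <- runif(n_raters) >= config$miss_prob
    }
  }

  long <- tibble(
    rater_id = rep(sprintf("rater_%02d", seq_len(n_raters)), times = n),
    image_id = rep(image_ids, each = n_raters),
    call = as.integer(as.vector(call)),
    observed = as.vector(observed)
  )
  as_rater_panel(long[long$observed, c("rater_id", "image_id", "call")])
}

#' Simulate a full synthetic study
#'
#' Draws, in a single seeded RNG stream: ground truth, difficulty pairs,
#' CNN scores and a rater panel, per the configuration. Identical config
#' and seed give byte-identical outputs.
#'
#' @param config A `synthetic_config`.
#' @return A list with `predictions` (prediction tibble), `panel`
#'   (`rater_panel`), `difficulties` (tibble `machine`, `human`) and
#'   `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    truth <- gen_truth(config$n_images, config$incidence)
    diffs <- gen_difficulties(config$n_images, config$rho)
    machine_d <- config$machine_difficulty %||% diffs$machine
    human_d <- config$human_difficulty %||% diffs$human
    scores <- gen_cnn_scores(truth, machine_d, config$kappa)
    image_ids <- sprintf("img_%03d", seq_len(config$n_images))
    panel <- gen_panel(truth, human_d, config, image_ids = image_ids)
    list(
      predictions = as_prediction_set(
        tibble(image_id = image_ids, score = scores, truth = truth)),
      panel = panel,
      difficulties = tibble(machine = machine_d, human = human_d),
      config = config
    )
  })
}

#' Canonical dissociation fixture
#'
#' A shipped synthetic study reproducing the qualitative structure of a
#' reader study in which machine and human difficulty are dissociated:
#' 150 images at 29.7% incidence read by a 69-rater panel. Machine
#' difficulty is bimodal — most images are machine-easy (difficulty
#' U(0.05, 0.35)) but a machine-hard stratum (difficulty U(0.60, 0.95))
#' is drawn preferentially from the benign class
#' (P(hard | malignant) = 0.25, P(hard | benign) = 0.605, about half the
#' images overall), emulating a classifier whose uncertain cases are
#' dominated by benign mimickers. Human difficulty is mild
#' (U(0, 0.03)) and drawn independently of machine difficulty
#' (correlation 0), so the machine-hard stratum stays human-tractable.
#' The certainty partition's inner list is therefore enriched in
#' machine-hard items and the CNN's inner-sublist AUC falls well below
#' its outer-sublist AUC, while the panel performs comparably on both —
#' the dissociation that makes inner-list substitution profitable. The
#' panel is strong (per-rater sensitivity and specificity U(0.935, 0.99),
#' concentration `kappa = 20`): a regime in which the mean human
#' operating point beats the machine overall and outer-list substitution
#' leaves the curve close to the machine baseline.
#'
#' @param seed Integer seed (default 1); the fixture is a deterministic
#'   function of it (byte-identical on regeneration).
#' @return As [simulate_study()]: list with `predictions`, `panel`,
#'   `difficulties`, `config`.
#' @export
make_dissociation_fixture <- function(seed = 1L) {
  seed <- as.integer(seed)
  n <- 150L
  withr::with_seed(seed, {
    truth <- gen_truth(n, 0.297)
    hard <- runif(n) < ifelse(truth == 1, 0.25, 0.605)
    machine_d <- ifelse(hard, runif(n, 0.60, 0.95), runif(n, 0.05, 0.35))
    human_d <- runif(n, 0, 0.03)
    config <- synthetic_config(
      n_images = n, incidence = 0.297, n_raters = 69,
      rater_sensitivity = c(0.935, 0.99),
      rater_specificity = c(0.935, 0.99),
      kappa = 20,
      machine_difficulty = machine_d, human_difficulty = human_d,
      rho = 0, miss_prob = 0.05, seed = seed)
    scores <- gen_cnn_scores(truth, machine_d, config$kappa)
    image_ids <- sprintf("img_%03d", seq_len(n))
    panel <- gen_panel(truth, human_d, config, image_ids = image_ids)
    list(
      predictions = as_prediction_set(
        tibble(image_id = image_ids, score = scores, truth = truth)),
      panel = panel,
      difficulties = tibble(machine = machine_d, human = human_d),
      config = config
    )
  })
}
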