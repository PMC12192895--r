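Package: hybridroc
Title: Confidence-Partitioned Human-AI Hybrid Evaluation for Lesion Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating human-machine hybrid triage of dermoscopic
    skin-lesion classifiers. Partitions CNN malignancy scores by prediction
    certainty into inner (uncertain) and outer (confident) item lists,
    substitutes uncertain predictions with randomly sampled human rater
    responses, and evaluates the resulting hybrid classifier with
    Monte-Carlo-averaged ROC curves and AUC. Includes multi-rater panel
    handling (three-point checklist binarization, completion filtering,
    per-rater and mean operating points) and a synthetic study generator
    with independently tunable machine and human difficulty so every stage
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
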