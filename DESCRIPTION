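Package: placeborct
Title: Placebo Response Analysis for Randomized Controlled Trials with
    Momentary Pain Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for placebo-controlled trials in chronic pain
    that monitor symptoms with twice-daily app-based visual analogue scale
    ratings. Cleans ecological momentary assessment rating streams,
    stratifies subjects into placebo responders and non-responders with a
    within-subject permutation test, computes response magnitude and
    percent analgesia, screens questionnaire subscales against response,
    runs edgewise permutation statistics and Louvain consensus community
    detection on functional connectivity matrices, computes subcortical
    volume asymmetry, and predicts response with nested leave-one-out
    cross-validated support vector machines and LASSO regression including
    permutation-null calibration and consensus weight maps. A synthetic
    cohort generator with known ground truth makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    glmnet,
    igraph,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
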