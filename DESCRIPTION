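Package: audlearn
Title: Latent Performance States and Early Learner Classification in
    Auditory Category Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for auditory category-learning experiments
    in which participants learn a conjunction of two tone features (duration
    and direction of pitch change) by trial and error. Computes block and
    cumulative sensitivity/specificity coefficients from trial logs, fits
    one-dimensional Gaussian mixture models by EM with BIC-based selection
    of the number of latent performance states, assigns each trial block to
    a high/med/low performance state, tests response-button and
    target-configuration effects on high-performance block counts with
    Mann-Whitney U tests, and classifies learners versus non-learners from
    early-block features with a class-weighted gradient-boosted ensemble.
    Includes a design-faithful synthetic cohort generator (stimulus space,
    balanced trial schedules, Markov performance-state dynamics) so the
    whole pipeline can be exercised and tested without access to original
    behavioural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
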