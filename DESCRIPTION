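Package: plsvip
Title: Double Cross-Validated PLS-DA Stability Selection for LC-MS
    Lipidomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Variable selection and class-separation analysis for
    untargeted LC-MS lipidomics feature tables with a binary clinical
    outcome.  Implements total-ion-current normalization, blank and
    abundance filtering, autoscaling, NIPALS PLS1 discriminant models
    with venetian-blind cross-validation and RMSECV-driven latent
    variable selection, iterative VIP-threshold pruning inside a
    repeated double cross-validation (CV2) loop, frequency-based
    stability selection, one-way ANOVA F ranking with a permutation
    null FDR estimator, and PCA verification of group separation.
    Includes a synthetic cohort generator with planted discriminative
    features for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
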