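Package: itmeeg
Title: Information-Transfer, Multifractal and Spectral EEG Features with
    Tree-Based Cognitive Score Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts three families of features from multichannel
    resting-state EEG: within- and between-lead information transfer
    constants (kappa) over configurable delay grids, multifractal detrended
    fluctuation analysis (MF-DFA) Hoelder-spectrum summaries, and
    periodogram band power in the canonical frequency bands.  Couples the
    features to a CART regression pipeline (greedy variance-reduction
    trees, cost-complexity pruning, seeded 10-fold cross-validation with
    one-standard-error complexity selection) that trains on one EEG epoch
    and predicts cognitive subscores out-of-sample on a second epoch,
    reporting Pearson correlations with t statistics.  Includes readers
    and writers for EDF and delimited matrices, and seeded generators for
    power-law noise, fractional Gaussian noise, binomial multiplicative
    cascades and whole synthetic cohorts with known ground truth.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
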