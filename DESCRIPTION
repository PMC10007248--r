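Package: voxmmrc
Title: Dyspnea Severity Estimation from Controlled Telephone Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for estimating dyspnea severity on the
    modified Medical Research Council (mMRC) scale, classes 0-3, from short
    telephone-bandwidth recordings of three controlled vocalizations
    (/ae-ae/, /sa-sa/, one-to-thirty counting). Provides a severity-conditioned
    synthetic cohort generator, engineered vocal features (autocorrelation
    pitch tracking, Mel filterbank log energies, low-band log spectra with
    deltas), small neural classifiers with an ordinal stick-breaking output
    layer, hierarchical score fusion by min/max/mean/median/product rules, a
    speaker-disjoint k-fold training protocol with double validation subsets,
    and the associated evaluation metrics (accuracy, RMSE, binary false
    positive/negative rates, AUC).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
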