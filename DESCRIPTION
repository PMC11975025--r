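Package: wsitrust
Title: Trustworthy Tile-Based Whole-Slide Image Classification with
    Distance-Aware Uncertainty and Conformal Guarantees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for uncertainty-aware, abstention-capable classification of
    whole-slide images represented as bags of tile embeddings. Implements a
    spectral-normalized multilayer perceptron with a random-Fourier-feature
    Gaussian-process output layer (single-pass distance-aware uncertainty),
    an attention-based multiple-instance bag classifier, Monte Carlo dropout
    baselines, split conformal prediction and conformal risk control with
    coverage guarantees, ambiguity-guided elimination of uninformative tiles,
    out-of-distribution scoring and distribution-shift control, hierarchical
    tile/slide/patient aggregation, fairness-gap and attention-efficiency
    metrics, and a seeded synthetic cohort generator for end-to-end evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
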