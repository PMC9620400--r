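Package: agndesign
Title: Sequence Design of DNA-Stabilized Silver Nanocluster Fluorescence
    Colors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemistry-informed machine learning for DNA-stabilized silver
    nanoclusters (AgN-DNAs), whose fluorescence color is selected by the
    nucleobase sequence of the templating oligomer.  Ten-base DNA sequences
    are represented by gapped nucleobase-pair "staple" features, and an
    ensemble of one-versus-one L1-regularized linear classifiers trained on
    balanced subsamples predicts membership in five emission color classes
    (Dark, Green, Red, Far Red, NIR).  The package covers the full design
    loop: Gaussian peak fitting of well-plate emission spectra in energy
    space, training-set curation with k-means-derived class cutoffs,
    ensemble training and repeated cross-validation, shadow-feature
    importance analysis with per-class net importance scores, exhaustive
    screening of all 4^10 candidate sequences for a target color, and a
    planted-motif synthetic data generator so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
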