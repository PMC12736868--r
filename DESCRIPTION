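Package: bladdersim
Title: In-Silico Bioimpedance Modelling of Bladder Volume Across Anatomies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and analysis pipeline for bioimpedance-based
    bladder volume monitoring. Builds virtual cylindrical torso anatomies
    spanning a grid of waist circumferences and subcutaneous fat thicknesses,
    solves the quasi-static complex conduction problem with a complete
    electrode model for all tetrapolar measurement frames of a six-electrode
    belt, and derives voltage-change (delta-V) and voltage-change-ratio (VCR)
    signals against a near-empty-bladder baseline. Downstream stages
    characterize signal envelopes and anatomical correlations, fit
    patient-specific and generalized elastic-net volume estimators with
    feature-selection stability diagnostics (pairwise Jaccard, selection
    probability, stable sets), and apply linear and exponential anatomical
    frame-scaling normalizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
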