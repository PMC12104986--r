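Package: sdmaxent
Title: Presence-Only Maximum-Entropy Species Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits presence-background maximum-entropy (MaxEnt) species
    distribution models with linear, quadratic, product, hinge and
    threshold features and L1 regularization, and wraps them in the full
    analysis pipeline used for mapping a species' present and future
    range: occurrence gridding and protection summaries, collinearity
    driven predictor selection verified by variance inflation factors,
    spatial block cross-validation with AICc, AUC difference and the
    Continuous Boyce Index for tuning feature classes and regularization
    multipliers, threshold-based suitability classification with area
    accounting, climate-scenario projection with range-change and
    altitude statistics, and multivariate environmental similarity
    (MESS) extrapolation diagnostics. Includes a virtual-species
    landscape simulator so the whole pipeline can be exercised and
    tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
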