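Package: neurocode
Title: Localized and Distributed Neural Codes as Predictors of Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating region-of-interest (ROI) neural-code
    measures to individual differences in behavior. Implements two
    complementary ROI summaries of face-selective cortex -- overall
    selectivity (mean contrast Z across voxels) and between-category
    multivariate pattern dissimilarity (one minus the pattern correlation
    after mean-pattern removal) -- together with the inferential battery
    used in individual-differences neuroimaging: Pearson correlations,
    Steiger's test for dependent correlations (Meng-Rosenthal-Rubin form),
    multiple regression with standardized coefficients, balanced fourfold
    cross-validated brain-behavior prediction with a permutation null, and
    a within-category pattern-reliability noise control. Includes a
    block-design GLM with a gamma hemodynamic response function, seeded
    connected-component ROI extraction from Z maps, and a calibrated
    synthetic-cohort generator with independently planted univariate and
    multivariate brain-behavior effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    RNifti
Config/testthat/edition: 3
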