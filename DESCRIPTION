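Package: craniocorr
Title: Cranio-Cerebral Correspondence and Virtual 10-10 Positioning for the Infant Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how cortical macroanatomical landmarks and scalp
    10-20/10-10 positions co-develop in infancy. Provides virtual 10-20/10-10
    electrode placement on triangulated scalp surfaces from the four cranial
    fiducials (nasion, inion, pre-auricular points), generalized Procrustes
    analysis of landmark configurations with shape-space PCA and age regression,
    landmark distance-ratio statistics with exact Pearson p-values, and transfer
    of cortical landmarks to a template scalp via a three-vector decomposition
    with back-projection. Includes a synthetic infant-cohort generator with
    age-dependent anisotropic brain growth, configurable landmark drifts, and
    rater-noise emulation, so the full pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
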