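Package: gciplvf
Title: Structure-Function Analysis of Widefield OCT GCIPL Maps and 24-2 Visual Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools linking ganglion cell-inner plexiform layer (GCIPL) thickness maps
    from widefield optical coherence tomography to 24-2 visual field results across
    the glaucoma spectrum. Projects 24-2 stimulus locations onto fovea-centred
    thickness rasters with ocular-magnification and Henle-fibre displacement
    corrections, estimates ganglion cell counts over stimulus regions, fits segmented
    (broken-stick) structure-function regressions with Davies and nested-F tests,
    builds grid-square normative models with percentile flag maps and relative
    ("pattern-deviation"-style) thickness maps, classifies hemi-cluster visual field
    status via percentile proportions and PCA-plus-logistic cascades, and evaluates
    classifiers with DeLong AUROCC comparisons, Youden thresholds and clustered
    bootstrap confidence intervals. Includes a synthetic cohort generator so every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
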