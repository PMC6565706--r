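Package: icamorph
Title: Landmark-Based Morphometry of the Internal Carotid Artery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Six-landmark three-dimensional morphometry of the internal
    carotid artery (ICA): segment vectors, turning angles, arc-chord
    tortuosity and total flow-direction change computed from Slicer-style
    fiducial markups; cohort rules for genotype grouping, bilateral
    averaging, representative Suzuki grade and exclusion filtering; a
    nonparametric group-comparison battery (Kruskal-Wallis with
    Bonferroni-corrected pairwise rank-sum tests, Fisher's exact test,
    Lilliefors-calibrated normality screening); and a calibrated synthetic
    cohort generator that builds fiducial chains from internal coordinates
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
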