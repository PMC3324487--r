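Package: nephropep
Title: Urinary Peptidome Biomarker Discovery for Drug-Induced Nephrotoxicity
Version: 0.1.0
Authors@R:
    person("nephropep", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested reimplementation of a capillary electrophoresis mass
    spectrometry (CE-MS) urinary peptidomics analysis pipeline: calibration of
    peak lists against housekeeping and internal-standard peptides,
    tolerance-window matching of peptide features across samples into a
    consensus master list, Wilcoxon/Benjamini-Hochberg biomarker discovery
    with frequency filtering, a two-study marker selection workflow (temporal
    response screen, cross-toxin intersection, direction concordance), linear
    distance-2 and support-vector-machine panel classifiers with take-one-out
    cross-validation, migration-time plausibility filtering of sequence
    assignments, and Spearman correlation against histopathology and clinical
    chemistry endpoints. Ships a synthetic-cohort generator emulating rat
    gentamicin/cis-platin dosing designs so the whole pipeline is exercisable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
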