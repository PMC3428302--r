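Package: formamelt
Title: Formamide Melting Curves and Free-Energy Rules for Microarray Probe Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts formamide denaturation of DNA microarray probe/target
    duplexes with a two-state linear free energy model (LFEM). Duplex standard
    free energies come from a microarray-specific nearest-neighbor rule system
    covering perfect matches, single mismatches, bulged (insertion/deletion)
    mismatches, tandem mismatches, and relaxed terminal conformations.
    Includes probe-set constructors for tiling a 16S rRNA gene and inserting
    defined mismatches, preprocessing of replicated fluorescence intensity
    profiles over a formamide series, bi-level nonlinear calibration of the
    model with per-probe proportionality factors, a ProbeMelt-style probe
    design and specificity workflow, and a synthetic-data generator that
    emulates the experimental design so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
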