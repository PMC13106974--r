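Package: scmetal
Title: Single-Cell Elemental Quantification from LA-ICP-MS Transient Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies analyte mass (femtograms) in individual cells from
    time-resolved laser-ablation ICP-MS intensity traces. Implements
    blank-derived background thresholding, transient peak boundary detection
    and integration per ablation event, external calibration against gelatin
    micro-droplet standards with piecewise-linear drift correction, limits of
    detection and quantification, conversion of bulk ICP-MS digests to
    per-cell masses, group summaries with Mann-Whitney comparisons, and a
    seeded Poisson trace simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'trace-io.R'
    'config.R'
    'threshold.R'
    'peaks.R'
    'quantify.R'
    'calibration.R'
    'drift.R'
    'bulk.R'
    'simulate.R'
    'stats.R'
    'report.R'
    'pipeline.R'
    'scmetal-package.R'
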