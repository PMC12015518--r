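Package: prmsched
Title: Scheduled Parallel Reaction Monitoring Assays from DIA Translation Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds scheduled parallel-reaction-monitoring (PRM) assays for
    nominal-mass instruments from data-independent-acquisition (DIA)
    "translation libraries". Ranks candidate peptides by the intensity of
    their third-largest fragment ion, re-calibrates library retention times
    against anchors from a recent DIA injection, and places targets with a
    greedy, density-constrained scheduler that respects per-protein caps.
    Includes acquisition feasibility arithmetic (cycle time, maximum ion
    injection time, points per peak, gas-phase-fractionation isolation
    windows), design tools for dimethyl-labeled matrix-matched calibration
    backgrounds, and calibration-curve figures of merit: bilinear LoD/LoQ
    fits, percent coefficients of variation, and all-pairs log2 fold
    changes. Seeded synthetic-data generators produce every input format
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
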