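Package: fgfrpanel
Title: Targeted-Panel Variant, Fusion and Copy-Number Calling with
    Clinical Association Statistics for Nondiffuse Glioma Cohorts
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of the computational core of a
    clinical FGFR1/FGFR3 immunohistochemistry and targeted-sequencing study
    in ependymoma and pilocytic astrocytoma. Provides a synthetic-data
    generator for amplicon-panel reads (with spike-in point mutations, gene
    fusions and copy-number changes) and clinical cohorts; a simple
    seed-and-extend read aligner with SAM import/export; per-site pileups
    with a background-error-calibrated mutation filter; a split-anchor
    rearrangement detector; control-amplicon-normalised copy-number log
    ratios; and the cohort statistics layer (exact and Monte-Carlo Fisher
    tests, Kaplan-Meier, log-rank, and forward likelihood-ratio stepwise
    Cox regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
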