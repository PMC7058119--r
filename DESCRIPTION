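Package: scnapop
Title: Subclonal Reconstruction of Tumors from Somatic Copy-Number Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs tumor subclonal populations from somatic copy-number
    alterations (SCNAs) called on tumor/normal next-generation sequencing data.
    Provides an invertible log-linear GC-bias correction of the tumor/normal
    read-count ratio, an analysis of the solution space of the subclonal
    frequency equations, a clustering-based filter that removes false-positive
    SCNA breakpoints, detection of copy-neutral baseline segments, and Bayesian
    inference of per-segment absolute copy number and subclonal frequency under
    a tree-structured stick-breaking Dirichlet-process prior via MCMC, with an
    alternative flat (uniform-tree) mode for non-ISA data.  Includes a
    count-level simulator with known clone trees for validation, and a
    command-line pipeline wiring all stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
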