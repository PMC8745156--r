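Package: mthfrvar
Title: Structural Annotation of MTHFR Deficiency Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural annotation of missense variants of
    human methylenetetrahydrofolate reductase (MTHFR, UniProt P42898)
    associated with MTHFR deficiency. Implements a consensus free-energy
    (ddG) destabilization classifier over three per-method predictions,
    Shrake-Rupley solvent-accessible surface area with relative
    accessibility and exposure classification, homodimer interface
    detection by buried surface area, physicochemical variation-type
    fingerprints per protein domain with a pseudocount chi-square
    homogeneity test, and a light profile model of the regulatory domain
    built from a multiple sequence alignment. Ships a transcription of the
    published 72-variant annotation table and deterministic synthetic
    generators (toy structures, toy dimers, simulated variant tables,
    simulated alignments) so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
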