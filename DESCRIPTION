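Package: apmsquant
Title: Spectral-Count Quantitation and Interactor Calling for AP-MS Pull-Downs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for affinity-purification mass spectrometry
    (AP-MS) pull-down experiments quantified by spectral counting. Filters
    peptide-spectrum matches with per-engine score thresholds (Mascot ion
    score, Sequest XCorr/deltaCn, X!Tandem expectation), infers protein
    groups by parsimony, computes normalized spectral counts (nSC), calls
    bait-specific interactors against resin-only controls, partitions and
    intersects PDZ-domain hits across samples, and computes membrane-fraction
    fold-enrichment statistics for wild-type versus PDZ-binding-motif-deleted
    receptor constructs. Includes a synthetic PSM generator with ground-truth
    sidecars for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
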