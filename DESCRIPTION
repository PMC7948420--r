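Package: ptmforge
Title: Post-Translational Modification Survey Pipeline for Histone
    Methylation Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a mass-spectrometry-based survey of
    post-translational modifications on histone methyltransferases and
    demethylases. Provides propionylation-aware peptide mass and m/z
    arithmetic, multi-protease in-silico digestion, peptide-spectrum-match
    quality filtering and site collation, per-residue sequence coverage
    mapping, extracted-ion-chromatogram peak integration with relative
    occupancy and methylation-state stoichiometry, site contextualization in
    disorder tracks, domains and cross-species alignments (free-end-gap
    pairwise alignment), an N-terminal net-charge model, proportional-odds
    ordinal regression with an adjacent-category alternative and likelihood
    ratio test, threshold-driven assembly of a draft kinase-enzyme regulatory
    network, and seeded synthetic-data generators with recorded ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
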