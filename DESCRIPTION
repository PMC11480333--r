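Package: phosphodyn
Title: Stage-Resolved Phosphoproteome Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for stage-resolved (time-course)
    phosphoproteomics with matched proteome quantification. Implements
    phosphosite classification by localization probability, calibration of
    phosphosite intensities against protein abundance, differential-regulation
    calling with Benjamini-Hochberg false discovery rate control and
    fold-change gates, fuzzy c-means clustering of temporal profiles,
    cross-species phosphosite conservation screening on 13-mer sequence
    windows, novelty screening against reference site catalogs, and
    kinase-substrate network analysis (Fisher-exact substrate enrichment and
    substrate-based kinase activity inference). Ships a synthetic-data
    generator with known ground truth that emulates a three-stage, five
    replicate TMT-like oocyte maturation design, so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
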