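Package: phoswave
Title: TMT Phosphoproteome Time-Course Analysis with Kinase-Activity Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for multiplexed (TMT-style) proteome and
    phosphoproteome time courses of the budding-yeast meiotic divisions.
    Reads MaxQuant-dialect proteinGroups and Phospho (STY)Sites tables,
    performs reporter-channel median scaling, phospho-to-protein ratio
    normalization and two-batch correction, applies detection and
    localization filters, calls differential abundance against a reference
    timepoint or strain with explicit zero-intensity policies, clusters
    temporal profiles by Ward linkage with elbow-based cluster-count
    selection, matches and tests kinase consensus motifs (Fisher exact),
    builds position-specific residue-difference logos, discovers
    single-offset sub-motifs, and runs hypergeometric over-representation
    analysis. A synthetic-data generator with planted kinase-activity
    waves provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    limma,
    Biostrings,
    yaml
Config/testthat/edition: 3
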