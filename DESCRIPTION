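Package: metfam
Title: Fe/Cu Metalloprotein Fold-Family Inventories from Meta-Omic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds iron- and copper-metalloprotein reference sets by
    recursive traversal of a SCOPe-style structural-classification
    hierarchy, profiles metagenomic or metatranscriptomic reads against
    them with a translated Smith-Waterman search (bit-score filtering,
    fractional top-hit weighting, nirK/multicopper-oxidase splitting,
    minor-family clustering, per-100,000 protein-coding normalization),
    assigns read taxonomy by lowest common ancestor, and relates the
    resulting inventories to oxygen-zone and trace-metal geochemistry
    (Fe:Cu molar ratios, linear fits against dissolved oxygen, Spearman
    screens, rarefaction, and partial canonical correspondence analysis).
    Includes a synthetic-data generator so every stage is testable
    without external sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
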