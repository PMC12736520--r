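Package: delimetrics
Title: Integrative Species Delimitation Metrics for DNA Barcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative species delimitation in microalgae and other
    taxa: Kimura 2-parameter barcode distances with pairwise deletion,
    barcode-gap evaluation (distance range overlap, ROC/AUC with DeLong
    confidence intervals, Youden and gap-midpoint thresholds, identification
    efficiency), distance-threshold clustering and the K/theta rule with
    match/split/merge/mixture scoring of candidate partitions against a
    reference taxonomy, morphological trait binarization with Jaccard
    distances, per-trait Mantel tests and morphology-phylogeny congruence
    (CADM, Procrustes, Holm), compensatory base change detection in ITS
    secondary structures, and fatty-acid unsaturation/ANOVA statistics.
    Includes seeded synthetic-data generators for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
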