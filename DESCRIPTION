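Package: mirsvm
Title: Two-Stage Support Vector Machine Prediction of MicroRNA Targets
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts microRNA target genes from 3' UTR sequence alone with a
    two-stage support vector machine. Candidate target sites are enumerated
    under nine seed-match definitions (8mer, 7mer-A1, 7mer-m8, 6mer, single
    G:U wobble with the U on the miRNA or the target, single loop, and single
    bulge on either strand), overlaps are resolved by seed-type precedence,
    and each site is described by seed type, 3' supplementary pairing from a
    Needleman-Wunsch duplex alignment, local AU context, and positional
    features. A site-level polynomial-kernel SVM scores individual sites; its
    cross-validated discriminant values are re-encoded per gene as a 16-bin
    percentile distribution together with site-count and site-spacing
    features, and a linear-kernel SVM separates down-regulated from
    unaffected genes. Includes ROC and truncated-ROC evaluation,
    leave-one-feature-out ablation, and a synthetic benchmark generator that
    plants seed sites with a known repression mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pROC
Config/testthat/edition: 3
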