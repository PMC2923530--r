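Package: refstab
Title: Reference Gene Selection from Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Defines stably expressed reference (housekeeping) genes from
    heterogeneous multi-study expression compendia. Implements probe-level
    present/absent detection calls (discrimination scores with a one-sided
    exact Wilcoxon signed-rank test), an expressed-everywhere compendium
    filter, partitioned coefficient-of-variation stability screening with
    rank-based candidate selection, a geNORM-style validation engine
    (stability measure M, stepwise exclusion ranking, pairwise variation
    V and geometric-mean normalization factors) fed by qPCR Ct tables,
    replicate-averaged log2 clustering with average linkage, and a seeded
    synthetic compendium generator with planted ground truth so that every
    stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
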