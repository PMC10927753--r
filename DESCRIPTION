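Package: vuscope
Title: Ensemble Classification and Structural Stability Auditing of CHEK2
    Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational interpretation of CHEK2 missense
    variants of uncertain significance: a majority-vote ensemble classifier
    that compares the benign-verdict rate of 15 pathogenicity predictors
    against three operating-mode thresholds; per-column conservation and
    information content from multiple sequence alignments; detection of
    hydrogen bonds, salt bridges, cation-pi interactions, burial and
    inter-chain proximity on static protein structures; trajectory stability
    assessment via pairwise-RMSD clustering around a mutation site with
    replica-level stable/unstable and dimer bound/unbound calls; descriptive
    cohort statistics and qualitative cosegregation evaluation; and seeded
    synthetic-data generators for every input so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
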