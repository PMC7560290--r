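Package: refstab
Title: Reference-Gene Stability Evaluation for Relative qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates candidate reference genes for quantitative real-time
    PCR (qPCR) normalisation. Implements four stability algorithms
    (comparative delta-Ct, geNorm with pairwise-variation analysis,
    NormFinder-style variance decomposition, BestKeeper descriptive
    statistics), geometric-mean consensus ranking across algorithms,
    selection of the optimal number of reference genes from the Vn/Vn+1
    series, standard-curve amplification-efficiency estimation and
    2^-ddCt relative quantification with single- or multi-gene
    normalisation. Includes sequence utilities for duplicated (homeolog)
    gene copies in polyploids: pairwise identity, discovery of identical
    windows for primer placement, primer-constraint checks and exact-match
    in-silico PCR. A seeded simulator generates replicate-level Ct tables
    and dilution series with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
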