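Package: bccre
Title: Consensus Atlas Construction and Sequence Analysis of Brain-Active
    Candidate cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("bccre", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building a consensus atlas of brain-active candidate
    cis-regulatory elements (b-cCREs) from chromatin-accessibility z-scores,
    classifying elements by life stage and cell type, partitioning elements by
    multi-genome alignment-fraction conservation, weighting enhancer-validation
    evidence fractionally, computing permutation-based genomic interval
    enrichments, calling candidate transcription-factor binding sites from
    base-resolution importance tracks with a three-state hidden Markov model,
    and ranking motifs with a random-forest importance ensemble. Includes a
    synthetic-data generator with planted, recoverable structure so the whole
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
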