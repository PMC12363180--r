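Package: phannot
Title: Sequence-Clustering and Structural-Homology Annotation of Phage Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates large phage proteomes by clustering proteins from
    precomputed pairwise alignments with a greedy set-cover strategy,
    transferring structure-derived annotations from cluster representatives
    to all cluster members, and quantifying the result: sequence- and
    structure-based annotation rates, per-cluster structural purity
    (LDDT/TM-score means), Pfam and four-level EC consistency statistics,
    lowest-common-ancestor taxonomy summaries of structural homologs, and
    thresholded phage-host protein interaction networks built from
    ipTM/pTM confidence scores. Ships a seeded synthetic-fixture generator
    with planted ground truth so every pipeline stage is testable without
    database downloads, plus a command-line entry point that chains the
    stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
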