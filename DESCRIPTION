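Package: genprops
Title: Genome Properties Assignment and Phylogenetic Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models higher-order functional attributes of genomes
    (pathways, complexes, systems, guilds, metapaths and organizational
    categories) as ordered series of evidence-backed steps, and asserts
    each attribute as YES, PARTIAL or NO for a proteome from its
    InterProScan match table.  Includes a parser and writer for the DESC
    flatfile dialect and its concatenated release file, match-table input
    with a promiscuous-evidence filter, threshold-based assignment with
    summary, step-level and protein-centric reports, property-by-proteome
    profile matrices with numeric encoding, Gower distances and a
    permutation ANOSIM test, release-time quality-control checks with a
    curation evidence-selection heuristic, and a deterministic synthetic
    fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
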