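Package: metaortho
Title: Consensus Ortholog Group Prediction by Partition Intersection and Profile Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the ortholog-group predictions of several independent
    orthology methods into a consensus clustering. Seed groups are formed as
    exact intersections of the input partitions, iterating from all N methods
    down to pairs; unassigned proteins are then recruited into seed groups by
    comparison against position-specific scoring profiles built from each
    seed's multiple alignment, under E-value and alignment-coverage
    thresholds. Includes a modified best-reciprocal-hit input method, an
    evaluation suite (pairwise Jaccard of co-grouped pairs, fusion/fission
    accounting against curated reference groups, and information-content
    based functional-annotation conservation for GO and EC), and a seeded
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
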