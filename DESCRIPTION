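Package: foldbridges
Title: Consensus Networks of Structural Bridges Across Protein Fold Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibrates pairwise structural-alignment scores from multiple
    alignment methods to empirical posterior probabilities of SCOP fold
    co-membership, collapses domain-level similarities into fold-level
    "structural bridge" networks across probability thresholds, builds
    consensus networks over the methods, and analyses weighted centralities,
    Louvain communities and fold-age patterns on the resulting landscapes.
    Includes a synthetic-data generator that plants fold hierarchies,
    method-specific score distributions, inter-fold bridges, community
    structure and age assortativity so the whole pipeline is testable
    without external structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    bio3d,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
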