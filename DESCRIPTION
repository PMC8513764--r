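Package: treeislands
Title: Tree Islands and Island-Aware Consensus for Sets of Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects islands of trees -- connected components of a
    distance-threshold graph over a set or multiset of phylogenetic
    topologies -- and provides consensus summaries that mitigate large
    island bias. Islands can be found from any pairwise tree distance
    (Robinson-Foulds by default) or directly by nearest-neighbor
    interchange (NNI) neighborhood merging. Summaries include
    partitioned-by-island, weighted-by-island-size and
    rarefied-by-island-size majority-rule consensus trees, island
    size/mass/density statistics, NNI-graph average degree, and a local
    instability incidence and correlation analysis. A synthetic
    generator plants multi-island tree distributions with known
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
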