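Package: cnpdist
Title: Copy-Number Profile Distances for Cancer Clone Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distances between copy-number profiles (CNPs) evolving by
    multi-copy segmental amplifications and deletions, for distance-based
    reconstruction of cancer clone phylogenies. Implements the flat-interval
    factor-2 approximation of the segmental event distance and its greedy
    merge-event improvement, null-position reductions that preserve the
    distance, the unit-event (MEDICC-model) distance via dynamic programming,
    an exact breadth-first search oracle for small instances, a simulator that
    evolves chromosome strings by tandem duplications and deletions along
    random clone trees, and a neighbor-joining plus Robinson-Foulds evaluation
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
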