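Package: repscan
Title: Structural Delineation of Rolling-Circle Replication Initiator
    Families and Detection of Bipartite Replication Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based classification of rolling-circle
    replication (RCR) initiator proteins and for locating the bipartite
    DNA origins they act on. Provides greedy sequence-redundancy
    clustering with alignment-based identity, rigid-body superposition
    and TM-score structural alignment, an all-vs-all structural
    similarity matrix, a deterministic geometric structural alphabet
    with progressive alignment, UPGMA dendrograms with column-bootstrap
    supports, sequence-logo conservation profiles for catalytic motifs,
    and a scanner for inverted-repeat + hairpin origin architectures
    with mutation-effect classification. A synthetic-data generator
    produces protein families and replicons with known ground truth so
    the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ape,
    Biostrings,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
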