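Package: homoplasr
Title: Phylogenetic Clustering of Parallel and Divergent Amino Acid Substitutions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects changes in single-position fitness landscapes from the
    phylogenetic clustering of homoplasies. Reconstructs marginal maximum
    likelihood ancestral amino acid states on a rooted tree under an
    empirical exchangeability model with discrete-gamma rate heterogeneity,
    maps substitutions onto edges, classifies phylogenetically independent
    pairs of substitutions sharing an ancestral state as parallel or
    divergent, and compares their mid-edge phylogenetic distances with
    matched subsampling, distance-binned parallel-to-divergent (P/D) ratio
    curves, and site bootstrap confidence intervals. Includes an event-level
    sequence evolution simulator with truth logging, supporting a
    time-homogeneous null, clade-specific substitution matrices, and a
    positive control in which the set of permitted amino acids at a site
    switches along branches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
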