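Package: peatviromics
Title: Peat Virome Community Ecology from Contigs to Phylogenetic Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a peat viral ecology workflow:
    dereplication of viral contigs into species-level viral populations (vOTUs)
    by the 95 percent identity / 85 percent coverage rule, breadth-gated
    detection and trimmed-mean abundance tables from read alignments,
    genus-level gene-sharing viral clusters (hypergeometric similarity plus
    Markov clustering) with taxonomy transfer and habitat-overlap summaries,
    CRISPR spacer-protospacer virus-host linkage, negative-binomial
    likelihood-ratio differential abundance across peat depth with trait
    enrichment, community-ecology statistics, and the Fritz-Purvis D statistic
    for phylogenetic dispersion of binary traits. A seeded synthetic community
    generator provides planted-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    ape,
    vegan,
    igraph,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
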