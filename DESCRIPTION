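Package: cogevol
Title: Comparative Evolution of Gene Families Across Dicots and Grasses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of a transcription-factor
    gene family across dicot and grass genomes: clustering of orthologous groups
    from reciprocal best-hit (BeT) triangles, alignment-quality filtering and
    neighbor-joining trees on JTT distances with bootstrap, gene-tree/species-tree
    reconciliation with ancient/recent duplication classification and ancestral
    copy-number reconstruction, and codon-model tests of divergent selection
    (pairwise dN/dS, branch models, M3 site mixtures, and a Markov-modulated
    M3+S1 switching model). A synthetic-data generator with known gene birth-death
    histories and selection regimes provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
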