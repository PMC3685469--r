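Package: prokphylo
Title: Comparative Genomics Across the Archaebacterial-Eubacterial Divide
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for four comparative-genomics analyses of deep prokaryote
    evolution: a census of 4Fe-4S cluster-forming cysteine motifs (CX2CX2CX3C
    and spacer variants) across proteomes; presence calling of quinone and
    haem biosynthesis pathways from similarity-search hit tables, including
    the haem-d1 reassignment rule; a taxonomic stringency grid counting
    ortholog families jointly distributed across archaebacterial and
    eubacterial groups under an all-pairs identity filter; and a gene-tree
    concordance analysis that measures how often each node of a concatenated
    (supermatrix) tree is recovered by the underlying single-gene trees.
    A synthetic-data generator produces genomes, families, proteomes, hit
    tables and gene trees with known ground truth so that every stage of the
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
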