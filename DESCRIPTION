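Package: mulred
Title: Conflict-Free Quartet Information and Reduction of Multi-Labeled
    Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-labeled phylogenetic trees (MUL-trees) carry two or more
    leaves with the same taxon label and can therefore display conflicting
    topologies for the same taxa.  mulred measures the conflict-free quartet
    information content of a MUL-tree, reduces any MUL-tree to its unique
    maximally reduced form (MRF) while preserving that information exactly,
    and optionally restricts the result to once-occurring labels to obtain a
    singly-labeled tree for supertree and supermatrix pipelines.  Includes
    Newick input/output tolerant of duplicate labels, a brute-force reference
    reducer used as a testing oracle, a seeded simulator of gene-family-like
    MUL-trees, corpus-level taxon-loss accounting, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
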