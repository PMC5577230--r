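Package: actinoprint
Title: Diversity and Biosynthetic-Potential Fingerprinting of Cultivable
    Actinobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of the sequence-based workflow used to
    characterize cultivable Actinobacteria collections: operational taxonomic
    unit (OTU) clustering of 16S rRNA genes at fixed identity thresholds,
    neighbor-joining phylogenetics with bootstrap support, in-silico PCR with
    degenerate primers targeting nonribosomal peptide synthetase (NRPS) and
    type II polyketide synthase (PKS-II) loci, amplified-fragment restriction
    fingerprinting with a densitometry band-scoring model, Jaccard/UPGMA
    grouping of restriction profiles, and correlation of biosynthetic-gene
    presence with antibacterial activity as a tripartite network. A seeded
    synthetic-community generator produces isolate collections with planted
    OTU, gene-prevalence and activity structure so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    rlang,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
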