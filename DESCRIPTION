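Package: akkpop
Title: Population Genomics of Akkermansia-Like Species Complexes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of closely related gut
    bacterial species such as the Akkermansia genus: MinHash-based average
    nucleotide identity and species-level genome binning, de novo gene-family
    clustering and clade-specific marker selection, marker-based metagenomic
    profiling, CRISPR spacer-to-phage matching with protospacer adjacent motif
    (PAM) reconstruction, viral-cluster construction and breadth-of-coverage
    detection, distance-based phylogenetics with Dollo gene-loss parsimony,
    subspecies delineation, and random-effects meta-analysis of host-phenotype
    associations (Fisher Z, Paule-Mandel). Ships a seeded synthetic-data
    generator that plants species structure, marker genes, CRISPR-phage links
    and cohort effects with machine-readable ground truth, so that every stage
    can be validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    phangorn,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
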