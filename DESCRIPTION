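Package: hirumine
Title: Homology Mining and Classification of Leech Antithrombotic Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for identifying antithrombotic
    gene families (hirudin, antistasin, the hirustasin superfamily, HMEI and
    further families of leech salivary anticoagulants) in genome
    assemblies. Provides affine-gap local and global protein alignment with
    BLOSUM62 and a similarity-index score, six-frame archetype homology
    scanning, spliced CDS-to-genome gene-model reconstruction with GT..AG
    introns, evidence/ab-initio model merging with duplicate removal,
    pseudogene flagging, cysteine-scaffold and internal-tandem-repeat
    validation, a signal-peptide heuristic, neighbor-joining subtype and
    activity-clade classification, per-family gene catalogues, and a seeded
    synthetic-genome generator with planted genes for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
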