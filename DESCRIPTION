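Package: satellitome
Title: Satellite DNA Discovery, Quantification and Comparative Evolution from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the satellite DNA repertoire (satellitome) of a
    genome from unassembled short reads and to compare repertoires across species.
    Discovers tandem-repeat families by iterative k-mer-graph detection and read
    subtraction, estimates genomic abundance and Kimura 2-parameter divergence of
    each family by read-to-consensus alignment (including repeat landscapes),
    curates a named catalog with same-variant/variant/superfamily similarity tiers,
    and compares catalogs across species via conserved-family detection, K2P and
    Jukes-Cantor distances, and consensus turnover rates (CTR = K/2T). A seeded
    synthetic-data generator plants tandem arrays with known abundance and
    divergence in paired-end read libraries so every stage is testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    data.table,
    tibble,
    dplyr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
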