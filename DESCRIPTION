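Package: duplexr
Title: Reference-Free Consensus Calling and Simulation for Duplex Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing duplex sequencing data without a reference
    genome. Paired-end reads carrying random 12-bp duplex tags are grouped
    into strand-specific families under an order-normalised canonical
    barcode, aligned within families, and reduced to single-stranded (SSCS)
    and duplex (DCS) consensus sequences, with quality-aware majority
    calling, IUPAC reconciliation of strand disagreements and ambiguity
    trimming. Includes an in silico duplex sequencing simulator (PCR
    amplification trees with per-cycle polymerase errors, barcode and
    linker construction, ground-truth output), an analytic model of barcode
    sequencing errors and the singleton families they create, and
    post-processing of strand-stratified allele counts (minor allele
    frequency and strand bias filters) for low-frequency variant studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
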