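Package: ulvapop
Title: Organellar Population Genomics of Foliose Ulva from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organellar population genomics of foliose Ulva
    (sea lettuce) from Illumina short reads: iterative reference-baited
    de novo assembly of circular chloroplast and mitochondrial genomes,
    ungapped read mapping with pileup-based variant calling and per-strain
    consensus construction, inter- and intra-specific SNP-density
    statistics over annotated coding sequence, SNP-matrix principal
    component analysis with single-linkage species delimitation and
    barcode-based species assignment, unique k-mer anchor synteny and
    inversion detection, neighbor-joining trees with bootstrap support
    and Robinson-Foulds agreement, and detection of inter-specific F1
    hybrids from pooled 45S rDNA allele frequencies combined with
    organellar homoplasmy checks. Includes a synthetic sequencing-design
    simulator (species panel, strains, one F1 hybrid, paired-end reads)
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
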