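Package: rdnaprof
Title: In Silico Profiling of 35S rDNA Arrays from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico analysis of tandemly repeated 35S rDNA
    in diploids and allopolyploids from whole-genome short reads: quality
    trimming, cost-parameterized read mapping with coverage and allele
    tallies, intragenomic SNP profiling, copy-number estimation from the
    genome proportion of mapped reads, homoeologue (subgenome) read
    classification via a diagnostic ITS1 window with neighbour-joining
    confirmation, haplotype diversity, and in-silico restriction/CAPS band
    prediction under methylation-sensitivity rules. Includes a synthetic
    rDNA-array and read simulator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
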