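Package: httscan
Title: Detection of Horizontal Transposon Transfer in Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inference pipeline for horizontal transposon transfer (HTT)
    of DNA transposons between vertebrate genomes. Detects transposable
    element (TE) copies by sensitive seed-and-extend nucleotide search,
    validates hAT structural hallmarks (terminal inverted repeats and
    target site duplications), measures Kimura 2-parameter divergence
    landscapes, quantifies TE-tree versus species-tree discordance, runs a
    flank-based presence/absence test for orthologous insertion sites, and
    integrates the evidence streams into per-species-pair HTT calls. A
    synthetic-genome simulator generates vertical-inheritance and HTT
    scenarios with known truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
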