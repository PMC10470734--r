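Package: mitoscreen
Title: Screening and Community Analysis of Large-RdRp Mitoviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for screening mitovirus-like genomes for
    unusually large RNA-dependent RNA polymerases (RdRps). Calls open reading
    frames under both the standard and the mold-mitochondrial genetic code
    (UGA = Trp), scans proteins and all six genome reading frames with a
    position-specific log-odds profile of a conserved N-terminal motif,
    computes tryptophan codon usage (%UGA), applies the large-duamitovirus
    rule (RdRp >= 900 aa plus the motif), and ordinates the three factors by
    principal component analysis. Community-scale analyses assign query RdRps
    to labelled reference proteins by Smith-Waterman local alignment, build
    site-by-group count matrices, run non-metric multidimensional scaling
    with permutation-based environment fitting, and test per-library
    co-occurrence correlations. A synthetic-data module generates
    mitovirus-like genomes, reference sets and metatranscriptome library
    metadata with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
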