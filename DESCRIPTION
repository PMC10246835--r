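Package: codonfit
Title: Codon-Composition Fitness Analysis for Horizontally Transferred Genes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for measuring how the synonymous-codon
    composition of a horizontally transferred gene maps to host fitness.
    Implements codon-optimality scores (CAI and tAI gene-level geometric
    means), a minimum-free-energy folding engine for 5'-end mRNA fragments
    with 30-nt sliding-window profiles, combinatorial ORG/MOD synonymous
    codon library enumeration and read counting, deep-sequencing enrichment
    statistics (log2 fold-change fitness proxies, weighted mean population
    fitness, Shannon diversity), feature-fitness rank associations,
    growth-curve and dose-response (IC50) fitting, a Moran-process
    serial-passage competition simulator, and a synthetic-data generator
    that emulates the selection experiment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
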