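Package: hydrosep
Title: Separation Capacity of Amino-Acid Hydrophobicity Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how well amino-acid hydrophobicity scales separate
    peptide pools of different secondary structure and membrane topology.
    Implements sliding-window hydrophobicity parameters (average
    hydrophobicity, hydrophobic moments at 100 and 180 degrees,
    alternating hydrophobicity, and an exact beta-strand score),
    five-dimensional convex point clouds with overlap-based separation
    scoring, UPGMA clustering of scales by correlation dissimilarity,
    in-silico tryptic digestion and secondary-structure pool assembly,
    k-mer pattern enrichment with Fisher tests and Benjamini-Hochberg
    correction, an evolutionary optimizer of scale values, and a seeded
    synthetic generator of annotated peptide pools for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
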