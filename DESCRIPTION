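Package: ventpop
Title: Population Genetics of Hydrothermal-Vent Copepod mtCOI Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-marker (mtCOI) population genetics of
    hydrothermal-vent meiofauna: codon-aware quality screening of
    protein-coding alignments (reading-frame and internal-stop checks
    against nuclear mitochondrial insertions), haplotype and nucleotide
    diversity with Jukes-Cantor correction and synonymous/nonsynonymous
    partitioning, demographic neutrality statistics (Tajima's D, Fu's Fs,
    R2, mismatch raggedness) with coalescent significance tests,
    Weir-Cockerham F_ST with permutation tests, statistical-parsimony
    haplotype networks, a coalescent generator of mtCOI-like synthetic
    samples, and a two-deme isolation-with-migration simulator with
    composite-likelihood parameter estimation on the joint site-frequency
    spectrum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    ape,
    Biostrings,
    igraph,
    geosphere,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
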