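Package: mirsnp
Title: SNP Landscapes of Human MicroRNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for studying single nucleotide polymorphisms
    (SNPs) inside microRNA precursor hairpins. Variants are projected into
    hairpin coordinates (precursor / mature / seed), SNP densities are
    compared across conservation tiers, genomic clusters and chromosomal
    fragile sites, each substitution is scored by the relative change in
    hairpin minimum free energy under a deterministic base-pair-weight
    folding engine, SNP burden is related to disease-association and QTL
    overlap counts, and allele-frequency panels are screened for
    population-differentiated SNPs with Monte-Carlo chi-square tests under
    Benjamini-Hochberg FDR control. A seeded synthetic-data generator
    produces complete input bundles with known planted truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    rtracklayer,
    Biostrings,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
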