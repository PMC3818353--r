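#' Published per-type substitution counts for human miRNA SNPs
#'
#' A reference table of the 12 ordered substitution types with their
#' published counts in seed regions, mature miRNAs and whole precursors,
#' bundled for aggregation checks and worked examples: feeding it through
#' [substitution_subtotals()] reproduces the published transition and
#' transversion subtotals and grand totals.
#'
#' @return Tibble (from_base, to_base, seed, mature, precursor), one row per
#'   ordered substitution type.
#' @export
reference_substitution_counts <- function() {
  df <- read_tsv_commented(system.file("extdata",
                                       "substitution_counts_reference.tsv",
                                       package = "mirsnp"))
  df$seed <- as.integer(df$seed)
  df$mature <- as.integer(df$mature)
  df$precursor <- as.integer(df$precursor)
  df
}

#' Published headline proportions of SNP-bearing miRNA regions
#'
#' Numerator/denominator pairs behind the reported headline percentages of
#' the genome-wide human miRNA SNP scan: precursors with at least one SNP
#' (961/1523 = 63%), mature miRNAs with a SNP (470/1919 = 24%), seed
#' regions with a SNP (170/1919 = 9%), precursors with fewer than 2 SNPs
#' (1013/1523 = 67%), clustered miRNAs (323/1523 = 21%) and substitutions
#' with no structural influence (236/1545 = 15%).
#'
#' @return Tibble (quantity, numerator, denominator, percent) where
#'   `percent` is computed with the package rounding rule [percent_of()].
#' @export
reference_headline_ratios <- function() {
  df <- tibble::tibble(
    quantity = c("precursors_with_snp", "matures_with_snp",
                 "seeds_with_snp", "precursors_lt2_snps",
                 "clustered_mirnas", "neutral_substitutions"),
    numerator = c(961L, 470L, 170L, 1013L, 323L, 236L),
    denominator = c(1523L, 1919L, 1919L, 1523L, 1523L, 1545L))
  df$percent <- percent_of(df$numerator, df$denominator)
  df
}
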