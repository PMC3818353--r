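#' Per-miRNA disease-association counts
#'
#' @param annotation A `mirna_annotation`.
#' @param diseases Association tibble (precursor_id, disease).
#' @return Tibble (precursor_id, disease_count) covering every annotated
#'   precursor (0 when unassociated). Counts sum to the number of unique
#'   association rows.
#' @export
disease_counts <- function(annotation, diseases) {
  per <- diseases |>
    dplyr::distinct(.data$precursor_id, .data$disease) |>
    dplyr::count(.data$precursor_id, name = "disease_count")
  annotation$precursors |>
    dplyr::select("precursor_id") |>
    dplyr::left_join(per, by = "precursor_id") |>
    dplyr::mutate(disease_count = dplyr::coalesce(.data$disease_count, 0L))
}

#' Compare precursor SNP densities of disease vs no-disease miRNAs
#'
#' miRNAs with at least one disease association form the disease group.
#' One-tailed Welch t-test of the alternative that the disease group's mean
#' precursor SNP density is lower than the no-disease group's.
#'
#' @param densities Density tibble from [region_densities()] (the precursor
#'   rows are used).
#' @param diseases Association tibble (precursor_id, disease).
#' @param tail Test tail (default "less": disease mean below no-disease).
#' @return A `mirsnp_test` with group means/SEMs in its extra fields.
#' @export
disease_density_compare <- function(densities, diseases, tail = "less") {
  pre <- dplyr::filter(densities, .data$region == "precursor")
  disease_ids <- unique(diseases$precursor_id)
  grp_d <- pre$density[pre$precursor_id %in% disease_ids]
  grp_n <- pre$density[!pre$precursor_id %in% disease_ids]
  if (length(grp_d) == 0 || length(grp_n) == 0) {
    abort("both the disease and no-disease groups must be non-empty")
  }
  welch_t(grp_d, grp_n, tail = tail)
}

grouped_means <- function(df, group_col, value_col) {
  df |>
    dplyr::group_by(group = .data[[group_col]]) |>
    dplyr::summarise(mean_value = mean(.data[[value_col]]),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' Correlation between SNP burden and disease-association counts
#'
#' Spearman rank correlation between per-miRNA SNP counts and disease
#' counts, plus the grouped-means curve (mean disease count within each
#' SNP-count group) used for reporting.
#'
#' @param df Tibble with columns `snp_count` and `disease_count`, one row
#'   per miRNA (>= 3 rows).
#' @param tail Test tail (default "two").
#' @return List of class `mirsnp_burden_cor`: `test` (a `mirsnp_test`,
#'   estimate = rho) and `curve` (tibble group, mean_value, n).
#' @export
snp_disease_correlation <- function(df, tail = "two") {
  test <- spearman_cor(df$snp_count, df$disease_count, tail = tail)
  structure(list(test = test,
                 curve = grouped_means(df, "snp_count", "disease_count"),
                 x = "snp_count", y = "disease_count"),
            class = "mirsnp_burden_cor")
}

#' Per-miRNA QTL overlap counts
#'
#' Number of QTL intervals intersecting each precursor (strand-agnostic,
#' half-open intervals; nested QTLs each count).
#'
#' @param annotation A `mirna_annotation`.
#' @param qtls QTL tibble (qtl_id, chrom, start, end).
#' @return Tibble (precursor_id, qtl_count).
#' @export
qtl_overlap_counts <- function(annotation, qtls) {
  pre <- dplyr::select(annotation$precursors, "precursor_id", "chrom",
                       "start", "end")
  if (nrow(qtls) == 0) {
    return(tibble::tibble(precursor_id = pre$precursor_id, qtl_count = 0L))
  }
  hits <- dplyr::inner_join(
    pre, dplyr::select(qtls, "qtl_id", "chrom", qstart = "start", qend = "end"),
    by = dplyr::join_by(chrom, start < qend, end > qstart),
    relationship = "many-to-many") |>
    dplyr::count(.data$precursor_id, name = "qtl_count")
  pre |>
    dplyr::select("precursor_id") |>
    dplyr::left_join(hits, by = "precursor_id") |>
    dplyr::mutate(qtl_count = dplyr::coalesce(.data$qtl_count, 0L))
}

#' Correlation between SNP burden and QTL overlap counts
#'
#' @param df Tibble with columns `snp_count` and `qtl_count`, one row per
#'   miRNA (>= 3 rows).
#' @param tail Test tail (default "two").
#' @return List of class `mirsnp_burden_cor` (see
#'   [snp_disease_correlation()]).
#' @export
qtl_snp_correlation <- function(df, tail = "two") {
  test <- spearman_cor(df$snp_count, df$qtl_count, tail = tail)
  structure(list(test = test,
                 curve = grouped_means(df, "snp_count", "qtl_count"),
                 x = "snp_count", y = "qtl_count"),
            class = "mirsnp_burden_cor")
}

#' @export
print.mirsnp_burden_cor <- function(x, ...) {
  cat("Spearman correlation of ", x$x, " vs ", x$y, ": rho = ",
      format(x$test$estimate), ", p = ", format(x$test$p), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mirsnp_burden_cor <- function(x, ...) tidy(x$test)
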