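#' Assign conservation tiers to miRNA families
#'
#' A family seen in at least 10 species is highly conserved, in 2-9 species
#' lowly conserved, and in a single species non-conserved.
#'
#' @param families Tidy family tibble (family, precursor_id, species_count)
#'   as from [read_families()].
#' @return Tibble (family, species_count, tier), one row per family.
#' @export
#' @examples
#' assign_tiers(tibble::tibble(family = c("f1", "f2"),
#'                             precursor_id = c("a", "b"),
#'                             species_count = c(12L, 3L)))
assign_tiers <- function(families) {
  fam <- dplyr::distinct(families, .data$family, .data$species_count)
  if (any(fam$species_count < 1)) abort("species_count must be >= 1")
  fam$tier <- dplyr::case_when(fam$species_count >= 10 ~ "highly",
                               fam$species_count >= 2 ~ "lowly",
                               TRUE ~ "non")
  tibble::as_tibble(fam)
}

#' Propagate family conservation tiers to individual miRNAs
#'
#' miRNAs without a family default to tier "non" (a hairpin known from a
#' single species only).
#'
#' @param annotation A `mirna_annotation`.
#' @param families Tidy family tibble (family, precursor_id, species_count).
#' @return Tibble (precursor_id, family, species_count, tier) for every
#'   annotated precursor.
#' @export
mirna_tiers <- function(annotation, families) {
  tiers <- assign_tiers(families)
  memb <- dplyr::distinct(families, .data$family, .data$precursor_id)
  out <- annotation$precursors |>
    dplyr::select("precursor_id") |>
    dplyr::left_join(memb, by = "precursor_id") |>
    dplyr::left_join(tiers, by = "family") |>
    dplyr::mutate(species_count = dplyr::coalesce(.data$species_count, 1L),
                  tier = dplyr::coalesce(.data$tier, "non"))
  tibble::as_tibble(out)
}

#' Detect miRNA genomic clusters
#'
#' Precursors on the same chromosome and strand are sorted by coordinate and
#' chained whenever the gap between consecutive intervals (downstream start
#' minus upstream end, negative gaps treated as 0) is strictly below
#' `threshold_bp`. Maximal chains of two or more precursors are clusters;
#' everything else is individual. Detection is invariant to input order.
#'
#' @param annotation A `mirna_annotation`.
#' @param threshold_bp Gap threshold in bp (default 10 kb; 20 kb is the
#'   common robustness preset).
#' @return Tibble (precursor_id, chrom, strand, start, end, cluster_id,
#'   clustered); `cluster_id` is NA for individual miRNAs.
#' @export
detect_clusters <- function(annotation, threshold_bp = 10000) {
  stopifnot(threshold_bp > 0)
  pre <- annotation$precursors |>
    dplyr::arrange(.data$chrom, .data$strand, .data$start, .data$end,
                   .data$precursor_id) |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::mutate(
      gap = pmax(.data$start - dplyr::lag(cummax(.data$end)), 0),
      new_run = is.na(.data$gap) | .data$gap >= threshold_bp,
      run = cumsum(.data$new_run)) |>
    dplyr::ungroup()
  pre$run_key <- paste(pre$chrom, pre$strand, pre$run, sep = "|")
  sizes <- table(pre$run_key)
  keep <- names(sizes)[sizes >= 2]
  cl_keys <- sort(unique(pre$run_key[pre$run_key %in% keep]))
  ids <- setNames(sprintf("cluster_%03d", seq_along(cl_keys)), cl_keys)
  pre$cluster_id <- ifelse(pre$run_key %in% keep, ids[pre$run_key],
                           NA_character_)
  pre$clustered <- !is.na(pre$cluster_id)
  tibble::as_tibble(pre[, c("precursor_id", "chrom", "strand", "start",
                            "end", "cluster_id", "clustered")])
}

#' Summarise clusters (members, span)
#'
#' @param clusters Output of [detect_clusters()].
#' @return Tibble (cluster_id, chrom, strand, span_start, span_end,
#'   n_members, members) with members ordered by coordinate.
#' @export
cluster_spans <- function(clusters) {
  clusters |>
    dplyr::filter(.data$clustered) |>
    dplyr::arrange(.data$start) |>
    dplyr::group_by(.data$cluster_id, .data$chrom, .data$strand) |>
    dplyr::summarise(span_start = min(.data$start), span_end = max(.data$end),
                     n_members = dplyr::n(),
                     members = paste(.data$precursor_id, collapse = ","),
                     .groups = "drop")
}

#' SNP densities of the flanking gaps inside miRNA clusters
#'
#' Each gap between consecutive cluster members is a density unit: `n` is
#' the number of distinct variants falling in the gap (genome-wide variant
#' positions restricted to cluster spans suffice), `L` the gap length.
#' Zero-length gaps are skipped.
#'
#' @param clusters Output of [detect_clusters()].
#' @param variants Variant tibble (0-based `pos`).
#' @return Tibble (region = "flanking", unit_id, cluster_id, n, L, density).
#' @export
flanking_density <- function(clusters, variants) {
  gaps <- clusters |>
    dplyr::filter(.data$clustered) |>
    dplyr::arrange(.data$cluster_id, .data$start) |>
    dplyr::group_by(.data$cluster_id, .data$chrom) |>
    dplyr::reframe(gstart = head(cummax(.data$end), -1),
                   gend = .data$start[-1]) |>
    dplyr::filter(.data$gend > .data$gstart)
  if (nrow(gaps) == 0) {
    return(tibble::tibble(region = character(), unit_id = character(),
                          cluster_id = character(), n = integer(),
                          L = integer(), density = double()))
  }
  gaps$unit_id <- paste0(gaps$cluster_id, "_gap",
                         stats::ave(seq_len(nrow(gaps)), gaps$cluster_id,
                                    FUN = seq_along))
  counts <- dplyr::inner_join(
    dplyr::distinct(variants, .data$snp_id, .data$chrom, .data$pos),
    gaps, by = dplyr::join_by(chrom, pos >= gstart, pos < gend)) |>
    dplyr::count(.data$unit_id)
  gaps |>
    dplyr::left_join(counts, by = "unit_id") |>
    dplyr::transmute(region = "flanking", unit_id = .data$unit_id,
                     cluster_id = .data$cluster_id,
                     n = dplyr::coalesce(.data$n, 0L),
                     L = as.integer(.data$gend - .data$gstart),
                     density = snp_density(.data$n, .data$L))
}

#' Label miRNAs by fragile-site overlap
#'
#' A miRNA is inside a fragile-site class when its precursor interval
#' intersects at least one site of that class; strand is ignored (cytogenetic
#' sites are strandless) and intervals are half-open, so a precursor that
#' merely abuts a site boundary is outside.
#'
#' @param annotation A `mirna_annotation`.
#' @param sites Fragile-site tibble from [read_fragile_sites()].
#' @return Tibble (precursor_id, in_any, in_common, in_rare).
#' @export
fragile_overlap <- function(annotation, sites) {
  pre <- dplyr::select(annotation$precursors, "precursor_id", "chrom",
                       "start", "end")
  hits <- dplyr::inner_join(
    pre, dplyr::select(sites, "chrom", sstart = "start", send = "end", "ftype"),
    by = dplyr::join_by(chrom, start < send, end > sstart),
    relationship = "many-to-many")
  lab <- hits |>
    dplyr::group_by(.data$precursor_id) |>
    dplyr::summarise(in_common = any(.data$ftype == "common"),
                     in_rare = any(.data$ftype == "rare"), .groups = "drop")
  out <- pre |>
    dplyr::select("precursor_id") |>
    dplyr::left_join(lab, by = "precursor_id") |>
    dplyr::mutate(in_common = dplyr::coalesce(.data$in_common, FALSE),
                  in_rare = dplyr::coalesce(.data$in_rare, FALSE),
                  in_any = .data$in_common | .data$in_rare)
  out[, c("precursor_id", "in_any", "in_common", "in_rare")]
}

#' Hypergeometric enrichment of multi-SNP miRNAs in fragile sites
#'
#' Upper-tail hypergeometric probability of seeing at least `k_overlap`
#' multi-SNP miRNAs inside fragile sites when `n_multi` miRNAs are drawn
#' from a population of `n_in + n_out` miRNAs of which `n_in` lie inside
#' sites. Computed exactly.
#'
#' @param n_in miRNAs inside fragile sites.
#' @param n_out miRNAs outside fragile sites.
#' @param n_multi miRNAs with at least 2 SNPs.
#' @param k_overlap multi-SNP miRNAs inside fragile sites.
#' @return The enrichment p-value.
#' @export
#' @examples
#' enrichment_test(5, 5, 4, 4)  # 5/210
enrichment_test <- function(n_in, n_out, n_multi, k_overlap) {
  hypergeom_upper_tail(N = n_in + n_out, K = n_in, n = n_multi, k = k_overlap)
}

#' Fragile-site enrichment counts and tests per site class
#'
#' Assembles, for each site class (any/common/rare), the counts feeding
#' [enrichment_test()]: miRNAs in and out of sites, miRNAs with >= `min_snps`
#' SNPs, and their overlap, against the universe of all annotated miRNAs.
#'
#' @param labels Output of [fragile_overlap()].
#' @param mapped Mapped-SNP tibble (distinct SNP ids per precursor counted).
#' @param min_snps Multi-SNP threshold (default 2).
#' @return Tibble (site_class, n_in, n_out, n_multi, k_overlap, p).
#' @export
fragile_enrichment <- function(labels, mapped, min_snps = 2) {
  per_pre <- mapped |>
    dplyr::distinct(.data$snp_id, .data$precursor_id) |>
    dplyr::count(.data$precursor_id)
  lab <- labels |>
    dplyr::left_join(per_pre, by = "precursor_id") |>
    dplyr::mutate(multi = dplyr::coalesce(.data$n, 0L) >= min_snps)
  one <- function(flag, cls) {
    n_in <- sum(lab[[flag]])
    n_out <- sum(!lab[[flag]])
    n_multi <- sum(lab$multi)
    k <- sum(lab$multi & lab[[flag]])
    tibble::tibble(site_class = cls, n_in = n_in, n_out = n_out,
                   n_multi = n_multi, k_overlap = k,
                   p = enrichment_test(n_in, n_out, n_multi, k))
  }
  dplyr::bind_rows(one("in_any", "any"), one("in_common", "common"),
                   one("in_rare", "rare"))
}

#' Intragenic / intergenic labels for miRNAs
#'
#' A miRNA is intragenic when its precursor interval intersects any
#' protein-coding gene interval (strand-agnostic, half-open intervals).
#'
#' @param annotation A `mirna_annotation`.
#' @param genes Gene tibble (chrom, start, end) from [read_genes_bed()].
#' @return Tibble (precursor_id, context) with context
#'   "intragenic"/"intergenic".
#' @export
genic_context <- function(annotation, genes) {
  pre <- dplyr::select(annotation$precursors, "precursor_id", "chrom",
                       "start", "end")
  if (nrow(genes) == 0) {
    return(tibble::tibble(precursor_id = pre$precursor_id,
                          context = "intergenic"))
  }
  hits <- dplyr::inner_join(
    pre, dplyr::select(genes, "chrom", gstart = "start", gend = "end"),
    by = dplyr::join_by(chrom, start < gend, end > gstart),
    relationship = "many-to-many")
  pre |>
    dplyr::transmute(precursor_id = .data$precursor_id,
                     context = ifelse(.data$precursor_id %in% hits$precursor_id,
                                      "intragenic", "intergenic"))
}
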