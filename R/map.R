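#' Project variants into hairpin coordinates
#'
#' Maps each variant onto every precursor whose interval covers it (a variant
#' overlapping k precursors yields k rows; per-precursor duplicates from
#' multi-placement input are collapsed). The hairpin position is the 0-based
#' offset from the precursor 5' end: for a minus-strand precursor spanning
#' `[start, end)` a forward-strand position `p` maps to `end - 1 - p`, and
#' alleles are reverse-complemented onto the sense strand before
#' transcription to RNA.
#'
#' The ancestral allele convention follows the hairpin reference: `anc_base`
#' is the base of the annotated precursor sequence at the mapped position
#' (not the chimpanzee-inferred allele, which travels separately in the
#' variant table). A substitution whose sense-strand reference base
#' disagrees with the hairpin sequence is flagged `ref_mismatch = TRUE`; it
#' stays in density counts but is excluded from substitution analyses.
#'
#' Mature membership lists every mature whose span covers the position; seed
#' membership applies to mature positions 2-8 (1-based from the mature 5'
#' end), i.e. offsets 1..7 within the mature.
#'
#' @param variants Variant tibble from [read_variants()].
#' @param annotation A `mirna_annotation`.
#' @return Tibble (snp_id, precursor_id, hairpin_pos, anc_base, mut_bases,
#'   in_mature, in_seed, vclass, validated, ref_mismatch). `mut_bases` is a
#'   comma-joined string of sense-strand RNA alternate bases (NA for
#'   non-substitutions); `in_mature`/`in_seed` are comma-joined mature ids
#'   ("" when empty).
#' @export
map_snps <- function(variants, annotation) {
  pre <- annotation$precursors
  hits <- dplyr::inner_join(
    variants, dplyr::select(pre, "precursor_id", "chrom", "start", "end",
                            "strand", "sequence"),
    by = dplyr::join_by(chrom, pos >= start, pos < end))
  if (nrow(hits) == 0) {
    return(empty_mapped())
  }
  hits <- dplyr::distinct(hits, .data$snp_id, .data$precursor_id,
                          .keep_all = TRUE)
  hits$hairpin_pos <- ifelse(hits$strand == "+", hits$pos - hits$start,
                             hits$end - 1L - hits$pos)
  hits$hairpin_pos <- as.integer(hits$hairpin_pos)
  hits$anc_base <- substr(hits$sequence, hits$hairpin_pos + 1L,
                          hits$hairpin_pos + 1L)

  to_sense <- function(allele, strand) {
    if (strand == "-") allele <- revcomp(allele, "dna")
    dna_to_rna(allele)
  }
  is_sub <- hits$vclass == "substitution"
  hits$sense_ref <- NA_character_
  hits$mut_bases <- NA_character_
  for (i in which(is_sub)) {
    hits$sense_ref[i] <- to_sense(hits$ref[i], hits$strand[i])
    alts <- strsplit(hits$alt[i], ",", fixed = TRUE)[[1]]
    hits$mut_bases[i] <- paste(vapply(alts, to_sense, character(1),
                                      strand = hits$strand[i]),
                               collapse = ",")
  }
  hits$ref_mismatch <- is_sub & hits$sense_ref != hits$anc_base
  if (any(hits$ref_mismatch)) {
    warn(paste0(sum(hits$ref_mismatch),
                " variant(s) disagree with the hairpin sequence; ",
                "excluded from substitution analyses"))
  }

  memb <- mature_membership(
    dplyr::select(hits, "snp_id", "precursor_id", "hairpin_pos"), annotation)
  agg <- memb |>
    dplyr::group_by(.data$snp_id, .data$precursor_id) |>
    dplyr::summarise(
      in_mature = paste(.data$mature_id, collapse = ","),
      in_seed = paste(.data$mature_id[.data$seed], collapse = ","),
      .groups = "drop")
  out <- dplyr::left_join(hits, agg, by = c("snp_id", "precursor_id"))
  out$in_mature <- dplyr::coalesce(out$in_mature, "")
  out$in_seed <- dplyr::coalesce(out$in_seed, "")
  tibble::as_tibble(out[, c("snp_id", "precursor_id", "hairpin_pos",
                            "anc_base", "mut_bases", "in_mature", "in_seed",
                            "vclass", "validated", "ref_mismatch")])
}

empty_mapped <- function() {
  tibble::tibble(snp_id = character(), precursor_id = character(),
                 hairpin_pos = integer(), anc_base = character(),
                 mut_bases = character(), in_mature = character(),
                 in_seed = character(), vclass = character(),
                 validated = logical(), ref_mismatch = logical())
}

# one row per (snp, precursor, covering mature), with seed flag
mature_membership <- function(pos_tbl, annotation) {
  dplyr::inner_join(pos_tbl, annotation$matures,
                    by = dplyr::join_by(precursor_id, hairpin_pos >= offset),
                    relationship = "many-to-many") |>
    dplyr::filter(.data$hairpin_pos < .data$offset + .data$length) |>
    dplyr::mutate(seed = .data$hairpin_pos >= .data$offset + 1L &
                    .data$hairpin_pos <= .data$offset + 7L) |>
    dplyr::select("snp_id", "precursor_id", "mature_id", "seed")
}

#' Classify a substitution as transition or transversion
#'
#' Purine<->purine (A, G) and pyrimidine<->pyrimidine (C, U) changes are
#' transitions; purine<->pyrimidine changes are transversions. Of the 12
#' ordered substitution types exactly 4 are transitions.
#'
#' @param from_base,to_base RNA bases (vectors recycle).
#' @return Character vector: "transition" or "transversion".
#' @export
#' @examples
#' classify_substitution("A", "G")
#' classify_substitution("G", "C")
classify_substitution <- function(from_base, to_base) {
  n <- max(length(from_base), length(to_base))
  from_base <- rep_len(toupper(from_base), n)
  to_base <- rep_len(toupper(to_base), n)
  if (!all(from_base %in% RNA_BASES) || !all(to_base %in% RNA_BASES)) {
    abort("substitution bases must be RNA bases (A, C, G, U)")
  }
  if (any(from_base == to_base)) {
    abort("a substitution needs two different bases")
  }
  ifelse((from_base %in% PURINES) == (to_base %in% PURINES),
         "transition", "transversion")
}

#' SNP density of a sequence
#'
#' Density = n / L: the number of SNPs in a sequence divided by its length
#' in base pairs.
#'
#' @param n SNP count(s), non-negative integer.
#' @param L Sequence length(s) in bp, positive integer.
#' @return Numeric density (SNPs per bp).
#' @export
#' @examples
#' snp_density(2, 100)
snp_density <- function(n, L) {
  if (any(L <= 0)) abort("sequence length must be positive")
  if (any(n < 0)) abort("SNP count must be non-negative")
  n / L
}

#' Per-region SNP density tables
#'
#' Computes one density record per precursor, per mature and per seed
#' region. `n` is the number of distinct SNP ids overlapping the unit
#' (alternate alleles of one SNP are never double-counted), `L` the unit
#' length in bp (seed length is 7 per mature). Units with zero SNPs are
#' included; downstream comparisons choose their own filtering (the global
#' density comparison of the source analyses uses only precursors with at
#' least one SNP).
#'
#' @param mapped Mapped-SNP tibble from [map_snps()].
#' @param annotation A `mirna_annotation`.
#' @return Tibble (region, unit_id, precursor_id, n, L, density) with
#'   region in precursor/mature/seed.
#' @export
region_densities <- function(mapped, annotation) {
  pre <- annotation$precursors
  mat <- annotation$matures

  per_pre <- mapped |>
    dplyr::distinct(.data$snp_id, .data$precursor_id) |>
    dplyr::count(.data$precursor_id)
  pre_tbl <- pre |>
    dplyr::left_join(per_pre, by = "precursor_id") |>
    dplyr::transmute(region = "precursor", unit_id = .data$precursor_id,
                     precursor_id = .data$precursor_id,
                     n = dplyr::coalesce(.data$n, 0L), L = .data$length)

  memb <- mature_membership(
    dplyr::select(mapped, "snp_id", "precursor_id", "hairpin_pos"), annotation)
  per_mat <- memb |>
    dplyr::distinct(.data$snp_id, .data$mature_id) |>
    dplyr::count(.data$mature_id)
  mat_tbl <- mat |>
    dplyr::left_join(per_mat, by = "mature_id") |>
    dplyr::transmute(region = "mature", unit_id = .data$mature_id,
                     precursor_id = .data$precursor_id,
                     n = dplyr::coalesce(.data$n, 0L), L = .data$length)

  per_seed <- memb |>
    dplyr::filter(.data$seed) |>
    dplyr::distinct(.data$snp_id, .data$mature_id) |>
    dplyr::count(.data$mature_id)
  seed_tbl <- mat |>
    dplyr::left_join(per_seed, by = "mature_id") |>
    dplyr::transmute(region = "seed", unit_id = .data$mature_id,
                     precursor_id = .data$precursor_id,
                     n = dplyr::coalesce(.data$n, 0L), L = 7L)

  out <- dplyr::bind_rows(pre_tbl, mat_tbl, seed_tbl)
  out$density <- snp_density(out$n, out$L)
  tibble::as_tibble(out)
}

#' Histogram of SNP counts per precursor
#'
#' @param mapped Mapped-SNP tibble.
#' @param annotation A `mirna_annotation` (supplies the zero-SNP precursors).
#' @return Tibble (n_snps, n_precursors) over all annotated precursors.
#' @export
snp_count_histogram <- function(mapped, annotation) {
  per_pre <- mapped |>
    dplyr::distinct(.data$snp_id, .data$precursor_id) |>
    dplyr::count(.data$precursor_id)
  counts <- annotation$precursors |>
    dplyr::left_join(per_pre, by = "precursor_id") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  counts |>
    dplyr::count(n_snps = .data$n, name = "n_precursors") |>
    dplyr::arrange(.data$n_snps)
}

#' Expand mapped SNPs into per-allele substitution events
#'
#' Keeps only clean substitutions (vclass substitution, no reference
#' mismatch) and expands multi-allelic records into one event per alternate
#' allele, so a SNP counts once for density but each allele once here.
#'
#' @param mapped Mapped-SNP tibble.
#' @return Tibble (snp_id, precursor_id, hairpin_pos, from_base, to_base,
#'   in_mature, in_seed, klass) with logical region flags.
#' @export
substitution_events <- function(mapped) {
  ev <- mapped |>
    dplyr::filter(.data$vclass == "substitution", !.data$ref_mismatch,
                  !is.na(.data$mut_bases)) |>
    tidyr::separate_rows("mut_bases", sep = ",") |>
    dplyr::filter(.data$mut_bases != .data$anc_base)
  tibble::tibble(
    snp_id = ev$snp_id, precursor_id = ev$precursor_id,
    hairpin_pos = ev$hairpin_pos,
    from_base = ev$anc_base, to_base = ev$mut_bases,
    in_mature = ev$in_mature != "", in_seed = ev$in_seed != "",
    klass = if (nrow(ev)) classify_substitution(ev$anc_base, ev$mut_bases)
            else character(0))
}

all_substitution_types <- function() {
  g <- expand.grid(from_base = RNA_BASES, to_base = RNA_BASES,
                   stringsAsFactors = FALSE)
  g <- g[g$from_base != g$to_base, ]
  g$klass <- classify_substitution(g$from_base, g$to_base)
  g <- g[order(g$klass == "transition", g$from_base, g$to_base), ]
  tibble::as_tibble(g)
}

#' Substitution count table across hairpin regions
#'
#' The 12 ordered substitution types counted in the seed, mature and whole
#' precursor columns. Every event counts once in the precursor column and
#' additionally in the mature/seed columns when it lies in those regions,
#' so seed <= mature <= precursor holds per row. Transversion and
#' transition subtotals and a grand total are appended via
#' [substitution_subtotals()].
#'
#' @param mapped Mapped-SNP tibble.
#' @return Tibble (from_base, to_base, substitution, seed, mature,
#'   precursor) with subtotal/total rows (NA from/to bases).
#' @export
substitution_table <- function(mapped) {
  ev <- substitution_events(mapped)
  types <- all_substitution_types()
  counts <- ev |>
    dplyr::group_by(.data$from_base, .data$to_base) |>
    dplyr::summarise(seed = sum(.data$in_seed), mature = sum(.data$in_mature),
                     precursor = dplyr::n(), .groups = "drop")
  tbl <- types |>
    dplyr::left_join(counts, by = c("from_base", "to_base")) |>
    dplyr::mutate(dplyr::across(c("seed", "mature", "precursor"),
                                \(x) dplyr::coalesce(x, 0L))) |>
    dplyr::select(-"klass")
  substitution_subtotals(tbl)
}

#' Append transition/transversion subtotals to a per-type count table
#'
#' Takes any table with `from_base`/`to_base` columns (one row per ordered
#' substitution type) and numeric count columns, classifies each row with
#' [classify_substitution()], and appends a transversion subtotal, a
#' transition subtotal and a grand total row.
#'
#' @param tbl Tibble with from_base, to_base and numeric count columns.
#' @return The table with a `substitution` label column and three appended
#'   summary rows ("subtotal of transversion", "subtotal of transition",
#'   "total").
#' @export
substitution_subtotals <- function(tbl) {
  num_cols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  klass <- classify_substitution(tbl$from_base, tbl$to_base)
  label <- paste0(tbl$from_base, "->", tbl$to_base)
  base <- dplyr::bind_cols(tibble::tibble(from_base = tbl$from_base,
                                          to_base = tbl$to_base,
                                          substitution = label),
                           tbl[num_cols])
  sum_row <- function(keep, lab) {
    vals <- lapply(tbl[num_cols], function(x) sum(x[keep]))
    dplyr::bind_cols(tibble::tibble(from_base = NA_character_,
                                    to_base = NA_character_,
                                    substitution = lab),
                     tibble::as_tibble(vals))
  }
  dplyr::bind_rows(
    base[klass == "transversion", ],
    sum_row(klass == "transversion", "subtotal of transversion"),
    base[klass == "transition", ],
    sum_row(klass == "transition", "subtotal of transition"),
    sum_row(rep(TRUE, nrow(tbl)), "total"))
}
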