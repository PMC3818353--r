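#' Read a per-population allele panel
#'
#' The panel TSV (commented header) carries one row per (SNP, population)
#' cell, either as direct allele counts (columns `ref_count`, `alt_count`)
#' or as an alternate-allele frequency plus diploid sample size (columns
#' `freq`, `n`). Frequency rows are converted to counts as
#' `alt_count = round(freq * 2n)`, `ref_count = 2n - alt_count`.
#'
#' @param path File path.
#' @return Tibble (snp_id, population, ref_count, alt_count).
#' @export
read_panel <- function(path) {
  df <- read_tsv_commented(path)
  if (all(c("ref_count", "alt_count") %in% names(df))) {
    out <- tibble::tibble(snp_id = df$snp_id, population = df$population,
                          ref_count = as.integer(df$ref_count),
                          alt_count = as.integer(df$alt_count))
  } else if ("freq" %in% names(df)) {
    if (!"n" %in% names(df)) {
      abort("frequency panel rows require a diploid sample size column 'n'")
    }
    freq <- as.numeric(df$freq)
    n <- as.integer(df$n)
    if (any(is.na(freq) | freq < 0 | freq > 1)) {
      abort("allele frequency outside [0, 1] in panel")
    }
    if (anyNA(n)) abort("missing sample size with frequency input")
    alt <- as.integer(round(freq * 2L * n))
    out <- tibble::tibble(snp_id = df$snp_id, population = df$population,
                          ref_count = 2L * n - alt, alt_count = alt)
  } else {
    abort("panel must carry ref_count/alt_count or freq/n columns")
  }
  if (any(out$ref_count < 0 | out$alt_count < 0)) {
    abort("negative allele counts in panel")
  }
  if (anyNA(out$ref_count) || anyNA(out$alt_count)) {
    abort("non-integer allele counts in panel")
  }
  dup <- duplicated(out[, c("snp_id", "population")])
  if (any(dup)) abort("duplicate (snp, population) cells in panel")
  out
}

#' Write an allele panel
#' @param panel Tibble as from [read_panel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  write_tsv_commented(panel[, c("snp_id", "population", "ref_count", "alt_count")],
                      path)
}

#' Read a miRNA family table
#'
#' TSV (commented header) with columns `family`, `species_count` and
#' `members` (comma-separated precursor ids). The result is tidy: one row
#' per (family, precursor).
#'
#' @param path File path.
#' @return Tibble (family, precursor_id, species_count).
#' @export
read_families <- function(path) {
  df <- read_tsv_commented(path)
  out <- tidyr::separate_rows(df, "members", sep = ",")
  tibble::tibble(family = out$family, precursor_id = out$members,
                 species_count = as.integer(out$species_count))
}

#' Write a miRNA family table
#' @param families Tidy tibble (family, precursor_id, species_count).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_families <- function(families, path) {
  df <- families |>
    dplyr::group_by(.data$family, .data$species_count) |>
    dplyr::summarise(members = paste(.data$precursor_id, collapse = ","),
                     .groups = "drop") |>
    dplyr::select("family", "species_count", "members")
  write_tsv_commented(df, path)
}

#' Read a fragile-site table
#'
#' TSV (commented header) with columns `name`, `ftype` (common|rare) and
#' either resolved genomic coordinates (`chrom`, `start`, `end`, 1-based
#' inclusive) or a `cytoband` column to be resolved against a cytoband
#' table (see [read_cytobands()]). Fragile sites are strandless; they are
#' stored with strand `+`.
#'
#' @param path File path.
#' @param cytobands Optional cytoband tibble (cytoband, chrom, start, end;
#'   0-based half-open) used when the file names cytobands instead of
#'   coordinates.
#' @return Tibble (name, chrom, start, end, strand, ftype), 0-based
#'   half-open.
#' @export
read_fragile_sites <- function(path, cytobands = NULL) {
  df <- read_tsv_commented(path)
  if (!all(df$ftype %in% c("common", "rare"))) {
    abort("fragile-site ftype must be 'common' or 'rare'")
  }
  if (all(c("chrom", "start", "end") %in% names(df))) {
    out <- tibble::tibble(name = df$name, chrom = df$chrom,
                          start = as.integer(df$start) - 1L,
                          end = as.integer(df$end),
                          strand = "+", ftype = df$ftype)
  } else if ("cytoband" %in% names(df)) {
    if (is.null(cytobands)) {
      abort("fragile-site file names cytobands; supply a cytoband table")
    }
    out <- dplyr::inner_join(df, cytobands, by = "cytoband")
    if (nrow(out) < nrow(df)) {
      abort("unresolved cytoband names in fragile-site table")
    }
    out <- tibble::tibble(name = out$name, chrom = out$chrom,
                          start = as.integer(out$start),
                          end = as.integer(out$end),
                          strand = "+", ftype = out$ftype)
  } else {
    abort("fragile-site table needs chrom/start/end or cytoband columns")
  }
  out
}

#' Read a cytoband table
#'
#' TSV (commented header) with columns cytoband, chrom, start, end (1-based
#' inclusive), converted to 0-based half-open. A small synthetic example is
#' bundled at `system.file("extdata", "cytobands_toy.tsv", package = "mirsnp")`.
#'
#' @param path File path.
#' @return Tibble (cytoband, chrom, start, end).
#' @export
read_cytobands <- function(path) {
  df <- read_tsv_commented(path)
  tibble::tibble(cytoband = df$cytoband, chrom = df$chrom,
                 start = as.integer(df$start) - 1L, end = as.integer(df$end))
}

#' Read protein-coding gene intervals (BED)
#'
#' Standard BED: 0-based half-open, no conversion needed.
#'
#' @param path File path.
#' @return Tibble (gene_id, chrom, start, end).
#' @export
read_genes_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    gene_id = if (ncol(df) >= 4) as.character(df[[4]]) else paste0("gene_", seq_len(nrow(df))),
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]), end = as.integer(df[[3]]))
}

#' Write gene intervals as BED
#' @param genes Tibble (gene_id, chrom, start, end), 0-based half-open.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genes_bed <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chrom, genes$start, genes$end,
                     genes$gene_id), path)
  invisible(path)
}

#' Read a miRNA-disease association table
#'
#' TSV (commented header) with columns `precursor_id`, `disease`; one row
#' per association. Associations are expected at precursor level (mature
#' names must be resolved to their precursor upstream).
#'
#' @param path File path.
#' @return Tibble (precursor_id, disease), unique pairs.
#' @export
read_diseases <- function(path) {
  df <- read_tsv_commented(path)
  out <- dplyr::distinct(tibble::tibble(precursor_id = df$precursor_id,
                                        disease = df$disease))
  out
}

#' Read a QTL interval table
#'
#' TSV (commented header) with columns qtl_id, trait, chrom, start, end
#' (1-based inclusive), converted to 0-based half-open.
#'
#' @param path File path.
#' @return Tibble (qtl_id, trait, chrom, start, end).
#' @export
read_qtls <- function(path) {
  df <- read_tsv_commented(path)
  tibble::tibble(qtl_id = df$qtl_id, trait = df$trait, chrom = df$chrom,
                 start = as.integer(df$start) - 1L, end = as.integer(df$end))
}
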