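#' Read a variant table (VCF subset or 8-column TSV)
#'
#' Two dialects are supported. `"vcf"` is a VCF v4 subset: CHROM POS ID REF
#' ALT are used, INFO is ignored except for an optional `ANC=` key (chimp
#' ancestral allele) and a `VLD` flag (validated). `"tsv"` is the package's
#' documented 8-column schema: snp_id, chrom, pos (1-based), ref, alt
#' (comma-separated), class, validated (0/1), ancestral (`.` if unknown).
#'
#' Positions are converted to 0-based at this boundary. The variant class is
#' always re-derived from the allele lengths: `substitution` iff ref and
#' every alt are single valid bases, `indel` on any length difference, and
#' `other` for anything else (including unknown base symbols).
#' Multi-allelic records are kept as one row with comma-joined `alt`.
#'
#' @param path File path.
#' @param dialect "vcf" or "tsv".
#' @return Tibble (snp_id, chrom, pos, ref, alt, vclass, validated,
#'   ancestral); `pos` 0-based, `ancestral` NA when unknown.
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") {
    lines <- readLines(path)
    body_idx <- which(!startsWith(lines, "#"))
    body <- lines[body_idx]
    if (length(body) == 0) {
      return(empty_variants())
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 8L)) {
      abort(paste0("malformed VCF line ", body_idx[which(nf < 8L)[1]],
                   " in ", path, ": fewer than 8 fields"))
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:8))
    pos <- suppressWarnings(as.integer(m[, 2]))
    if (anyNA(pos)) {
      abort(paste0("malformed VCF line ", body_idx[which(is.na(pos))[1]],
                   " in ", path, ": non-integer POS"))
    }
    info <- m[, 8]
    anc <- stringr::str_match(info, "(?:^|;)ANC=([^;]+)")[, 2]
    out <- tibble::tibble(
      snp_id = m[, 3], chrom = m[, 1], pos = pos - 1L,
      ref = toupper(m[, 4]), alt = toupper(m[, 5]),
      validated = grepl("(^|;)VLD(;|$)", info),
      ancestral = toupper(anc))
  } else {
    df <- read_tsv_commented(path)
    need <- c("snp_id", "chrom", "pos", "ref", "alt", "class", "validated", "ancestral")
    if (!identical(names(df), need)) {
      abort(paste0("TSV variant dialect requires columns: ",
                   paste(need, collapse = ", ")))
    }
    pos <- suppressWarnings(as.integer(df$pos))
    if (anyNA(pos)) {
      abort(paste0("malformed TSV variant line ", which(is.na(pos))[1] + 1L,
                   " in ", path, ": non-integer pos"))
    }
    out <- tibble::tibble(
      snp_id = df$snp_id, chrom = df$chrom, pos = pos - 1L,
      ref = toupper(df$ref), alt = toupper(df$alt),
      validated = df$validated %in% c("1", "TRUE", "true"),
      ancestral = ifelse(df$ancestral %in% c(".", ""), NA_character_,
                         toupper(df$ancestral)))
  }
  out$ancestral <- ifelse(is.na(out$ancestral) | out$ancestral == ".",
                          NA_character_, out$ancestral)
  out$vclass <- classify_vclass(out$ref, out$alt)
  dplyr::relocate(out, "snp_id", "chrom", "pos", "ref", "alt", "vclass",
                  "validated", "ancestral")
}

empty_variants <- function() {
  tibble::tibble(snp_id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(), vclass = character(),
                 validated = logical(), ancestral = character())
}

classify_vclass <- function(ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)
  vapply(seq_along(ref), function(i) {
    r <- ref[i]
    a <- alts[[i]]
    if (nchar(r) == 0 || length(a) == 0) return("other")
    all_single <- nchar(r) == 1 && all(nchar(a) == 1)
    valid <- grepl("^[ACGT]+$", r) && all(grepl("^[ACGT]+$", a))
    if (all_single && valid) return("substitution")
    if (valid && (!all_single)) return("indel")
    "other"
  }, character(1))
}

#' Write a variant table
#'
#' Inverse of [read_variants()]: writes either the VCF v4 subset (with
#' `VLD`/`ANC=` INFO keys) or the 8-column commented-header TSV dialect,
#' converting positions back to 1-based.
#'
#' @param x Variant tibble as returned by [read_variants()].
#' @param path Output path.
#' @param dialect "vcf" or "tsv".
#' @return Invisibly, `path`.
#' @export
write_variants <- function(x, path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") {
    info <- ifelse(is.na(x$ancestral), "", paste0("ANC=", x$ancestral))
    info <- paste0(info, ifelse(x$validated & info != "", ";", ""),
                   ifelse(x$validated, "VLD", ""))
    info[info == ""] <- "."
    lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                     x$chrom, x$pos + 1L, x$snp_id, x$ref, x$alt, info)
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), path)
  } else {
    df <- tibble::tibble(snp_id = x$snp_id, chrom = x$chrom, pos = x$pos + 1L,
                         ref = x$ref, alt = x$alt, class = x$vclass,
                         validated = as.integer(x$validated),
                         ancestral = ifelse(is.na(x$ancestral), ".", x$ancestral))
    write_tsv_commented(df, path)
  }
  invisible(path)
}
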