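#' Read miRNA precursor + mature annotation (GFF3 + FASTA)
#'
#' Reads a miRBase-style annotation: a GFF3 file with precursor records
#' (type `miRNA_primary_transcript`, attribute `ID=`) and mature records
#' (type `miRNA`, attribute `Derives_from=` pointing at the precursor), plus
#' a FASTA file of hairpin sequences whose ids match the GFF3 precursor ids.
#'
#' External coordinates are 1-based inclusive and are converted to the
#' package-internal 0-based half-open convention at this boundary; no 1-based
#' coordinate escapes this module. FASTA sequences follow the miRBase
#' convention: they are the hairpin (sense-strand) sequence written 5'->3'
#' regardless of genomic strand, in DNA or RNA alphabet; DNA is transcribed
#' to RNA (T -> U) on read. For a minus-strand precursor the stored sequence
#' therefore equals the reverse complement of the forward-strand genome
#' slice, transcribed to RNA.
#'
#' @param gff_path Path to the GFF3 annotation.
#' @param fasta_path Path to the hairpin FASTA.
#' @return An object of class `mirna_annotation`: a list with
#'   * `precursors`: tibble (precursor_id, name, chrom, start, end, strand,
#'     sequence, length), 0-based half-open coordinates;
#'   * `matures`: tibble (mature_id, precursor_id, offset, length) with
#'     `offset` the 0-based start of the mature within the hairpin.
#' @details Mature records that do not fit inside their precursor are dropped
#'   with a warning; a precursor id present in the GFF3 but absent from the
#'   FASTA (or vice versa) is an error.
#' @export
read_mirna_annotation <- function(gff_path, fasta_path) {
  gff <- rtracklayer::readGFF(gff_path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)

  is_pre <- gff$type == "miRNA_primary_transcript"
  is_mat <- gff$type == "miRNA"
  if (!any(is_pre)) abort("no miRNA_primary_transcript records in GFF3")

  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  seq_chr <- dna_to_rna(as.character(seqs))
  names(seq_chr) <- ids

  pre <- tibble::tibble(
    precursor_id = as.character(gff$ID[is_pre]),
    name = as.character(if (!is.null(gff$Name)) gff$Name[is_pre] else gff$ID[is_pre]),
    chrom = as.character(gff$seqid[is_pre]),
    start = as.integer(gff$start[is_pre]) - 1L,  # 1-based inclusive -> 0-based half-open
    end = as.integer(gff$end[is_pre]),
    strand = as.character(gff$strand[is_pre])
  )
  if (!all(pre$strand %in% c("+", "-"))) abort("precursor strand must be + or -")
  missing_seq <- setdiff(pre$precursor_id, names(seq_chr))
  if (length(missing_seq) > 0) {
    abort(paste0("precursor ids missing from FASTA: ",
                 paste(head(missing_seq, 5), collapse = ", ")))
  }
  pre$sequence <- unname(seq_chr[pre$precursor_id])
  pre$length <- pre$end - pre$start
  bad_alpha <- !is_rna_string(pre$sequence)
  if (any(bad_alpha)) {
    abort(paste0("non-ACGU symbols in hairpin sequences: ",
                 paste(head(pre$precursor_id[bad_alpha], 5), collapse = ", ")))
  }
  bad_len <- nchar(pre$sequence) != pre$length
  if (any(bad_len)) {
    abort(paste0("FASTA length disagrees with GFF3 interval for: ",
                 paste(head(pre$precursor_id[bad_len], 5), collapse = ", ")))
  }

  mat <- tibble::tibble(
    mature_id = as.character(gff$ID[is_mat]),
    precursor_id = as.character(gff$Derives_from[is_mat]),
    chrom = as.character(gff$seqid[is_mat]),
    mstart = as.integer(gff$start[is_mat]) - 1L,
    mend = as.integer(gff$end[is_mat])
  )
  mat <- dplyr::inner_join(mat,
    dplyr::select(pre, "precursor_id", pstart = "start", pend = "end", "strand"),
    by = "precursor_id")
  mat$offset <- ifelse(mat$strand == "+", mat$mstart - mat$pstart, mat$pend - mat$mend)
  mat$length <- mat$mend - mat$mstart
  plen <- mat$pend - mat$pstart
  ok <- mat$offset >= 0L & (mat$offset + mat$length) <= plen
  if (any(!ok)) {
    warn(paste0("dropping matures not contained in their precursor: ",
                paste(mat$mature_id[!ok], collapse = ", ")))
  }
  mat <- mat[ok, c("mature_id", "precursor_id", "offset", "length")]
  mat$offset <- as.integer(mat$offset)
  mat$length <- as.integer(mat$length)

  structure(list(precursors = pre, matures = tibble::as_tibble(mat)),
            class = "mirna_annotation")
}

#' Construct a mirna_annotation from in-memory tibbles
#'
#' Used by the synthetic generator and by tests; performs the same invariant
#' checks as [read_mirna_annotation()].
#'
#' @param precursors Tibble with precursor_id, name, chrom, start, end,
#'   strand, sequence (0-based half-open, RNA sense sequence).
#' @param matures Tibble with mature_id, precursor_id, offset, length.
#' @return A `mirna_annotation` object.
#' @export
mirna_annotation <- function(precursors, matures) {
  precursors <- tibble::as_tibble(precursors)
  matures <- tibble::as_tibble(matures)
  precursors$length <- precursors$end - precursors$start
  stopifnot(all(precursors$end > precursors$start),
            all(precursors$strand %in% c("+", "-")),
            all(nchar(precursors$sequence) == precursors$length),
            all(is_rna_string(precursors$sequence)))
  plen <- setNames(precursors$length, precursors$precursor_id)
  stopifnot(all(matures$precursor_id %in% precursors$precursor_id),
            all(matures$offset >= 0),
            all(matures$offset + matures$length <= plen[matures$precursor_id]))
  structure(list(precursors = precursors, matures = matures),
            class = "mirna_annotation")
}

#' @export
print.mirna_annotation <- function(x, ...) {
  cat("miRNA annotation: ", nrow(x$precursors), " precursors, ",
      nrow(x$matures), " matures on ",
      length(unique(x$precursors$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Write a mirna_annotation back to GFF3 + FASTA
#'
#' Inverse of [read_mirna_annotation()]; coordinates are converted back to
#' 1-based inclusive GFF3 and sequences written as hairpin-sense RNA FASTA.
#'
#' @param ann A `mirna_annotation`.
#' @param gff_path,fasta_path Output paths.
#' @return Invisibly, the GFF3 path.
#' @export
write_mirna_annotation <- function(ann, gff_path, fasta_path) {
  pre <- ann$precursors
  mat <- dplyr::inner_join(ann$matures,
    dplyr::select(pre, "precursor_id", "chrom", pstart = "start", pend = "end", "strand"),
    by = "precursor_id")
  mat$gstart <- ifelse(mat$strand == "+", mat$pstart + mat$offset,
                       mat$pend - mat$offset - mat$length)
  pre_lines <- sprintf(
    "%s\tmirsnp\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    pre$chrom, pre$start + 1L, pre$end, pre$strand, pre$precursor_id, pre$name)
  mat_lines <- sprintf(
    "%s\tmirsnp\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Derives_from=%s",
    mat$chrom, mat$gstart + 1L, mat$gstart + mat$length, mat$strand,
    mat$mature_id, mat$precursor_id)
  writeLines(c("##gff-version 3", pre_lines, mat_lines), gff_path)
  fa <- as.vector(rbind(paste0(">", pre$precursor_id), pre$sequence))
  writeLines(fa, fasta_path)
  invisible(gff_path)
}
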