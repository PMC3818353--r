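RNA_BASES <- c("A", "C", "G", "U")
PURINES <- c("A", "G")

#' Reporting percentage
#'
#' Rounds `100 * n / d` to the nearest whole percent, halves away from zero.
#' This is the rounding rule used throughout the package's reports, e.g.
#' "961 of 1523 precursors carry a SNP" prints as 63.
#'
#' @param n Numerator count.
#' @param d Denominator count (> 0).
#' @return Integer percentage(s).
#' @export
#' @examples
#' percent_of(961, 1523)
percent_of <- function(n, d) {
  stopifnot(is.numeric(n), is.numeric(d), all(d > 0))
  as.integer(floor(100 * n / d + 0.5))
}

#' Reverse complement of a nucleic-acid string
#'
#' Works on DNA or RNA (T and U both complement to A; A complements to T for
#' DNA input, U for RNA input).
#'
#' @param x Character vector of sequences.
#' @param alphabet "dna" or "rna"; controls whether A maps to T or U.
#' @return Character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  a_to <- if (alphabet == "dna") "T" else "U"
  vapply(x, function(s) {
    bases <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    comp <- c(A = a_to, C = "G", G = "C", T = "A", U = "A", N = "N")
    if (!all(bases %in% names(comp))) {
      abort(paste0("cannot reverse-complement sequence with symbols outside ACGTUN: ", s))
    }
    paste(comp[bases], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Transcribe DNA to RNA (T -> U), uppercasing
#' @param x Character vector of sequences.
#' @return RNA-alphabet sequences.
#' @export
dna_to_rna <- function(x) {
  stringr::str_replace_all(toupper(x), "T", "U")
}

#' Back-transcribe RNA to DNA (U -> T), uppercasing
#' @param x Character vector of sequences.
#' @return DNA-alphabet sequences.
#' @export
rna_to_dna <- function(x) {
  stringr::str_replace_all(toupper(x), "U", "T")
}

is_rna_string <- function(x) {
  grepl("^[ACGU]+$", x)
}

#' Derive a per-stage child seed from a global seed
#'
#' One global seed fans out to independent per-stage seeds so that skipping a
#' stage never shifts another stage's random stream. The rule is a fixed
#' affine hash of the stage name, reduced modulo 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% (2^31 - 1))
}

# writers emit tab-separated UTF-8 with a commented header line
write_tsv_commented <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  body <- df
  for (nm in names(body)) {
    if (is.list(body[[nm]])) {
      body[[nm]] <- vapply(body[[nm]], paste, character(1), collapse = ",")
    }
  }
  lines <- c(header, do.call(paste, c(lapply(body, as.character), sep = "\t")))
  if (nrow(df) == 0L) lines <- header
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path, col_types = NULL) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) {
    abort(paste0("expected a commented header line in ", path))
  }
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- readr::read_tsv(path, skip = 1L, col_names = cols,
                        col_types = col_types %||% readr::cols(.default = "c"),
                        comment = "", progress = FALSE,
                        show_col_types = FALSE)
  tibble::as_tibble(df)
}
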