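#' Fold an RNA hairpin and report its minimum free energy
#'
#' The builtin engine is a deterministic weighted base-pair-maximisation
#' dynamic program (Nussinov-style) over non-crossing structures: pair
#' weights G:C = 3, A:U = 2, G:U = 1, minimum hairpin loop of 3 unpaired
#' bases, no lonely-pair prohibition, reported as `mfe = -(total weight)` so
#' that more negative means more stable. Ties are broken by preferring a
#' pair closing at the smallest 5' index, then the smallest 3' partner, so
#' output is bit-for-bit reproducible across platforms. It is not a
#' thermodynamic nearest-neighbour model; its energies are model units, not
#' kcal/mol.
#'
#' An external engine (any function honouring the same contract, e.g. a
#' wrapper around a thermodynamic folder such as [rnafold_engine()]) can be
#' plugged in via `fold_fn`.
#'
#' @param sequence RNA string (A/C/G/U), length >= 1.
#' @param engine "builtin" or "external".
#' @param fold_fn For `engine = "external"`: a function(sequence) returning
#'   a list with `structure` (dot-bracket) and `mfe` (scalar energy).
#' @param min_loop Minimum hairpin loop size (builtin engine; default 3).
#' @return List of class `fold_result`: `structure` (dot-bracket, same
#'   length as the sequence) and `mfe` (<= 0 for the builtin engine; 0 iff
#'   the open chain is optimal).
#' @export
#' @examples
#' fold_mfe("GGGAAACCC")
fold_mfe <- function(sequence, engine = c("builtin", "external"),
                     fold_fn = NULL, min_loop = 3) {
  engine <- match.arg(engine)
  if (length(sequence) != 1 || !is.character(sequence) || nchar(sequence) < 1) {
    abort("sequence must be a single non-empty string")
  }
  sequence <- toupper(sequence)
  if (!is_rna_string(sequence)) {
    abort("sequence must use the RNA alphabet (A, C, G, U)")
  }
  if (engine == "builtin") {
    res <- .fold_nussinov(sequence, min_loop)
  } else {
    if (!is.function(fold_fn)) abort("external engine needs a fold_fn")
    res <- fold_fn(sequence)
    if (!is.list(res) || is.null(res$structure) || is.null(res$mfe)) {
      abort("external fold_fn must return list(structure=, mfe=)")
    }
    if (nchar(res$structure) != nchar(sequence)) {
      abort("external fold_fn returned a structure of the wrong length")
    }
  }
  structure(list(structure = res$structure, mfe = as.numeric(res$mfe),
                 sequence = sequence, engine = engine),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", format(x$mfe), ")\n", sep = "")
  invisible(x)
}

#' External folding engine backed by the RNAfold program
#'
#' Returns a `fold_fn` suitable for `fold_mfe(engine = "external")` that
#' shells out to ViennaRNA's `RNAfold` for thermodynamic (kcal/mol)
#' energies. Requires `RNAfold` on the PATH.
#'
#' @param rnafold Path to the RNAfold executable.
#' @return A function(sequence) -> list(structure, mfe).
#' @export
rnafold_engine <- function(rnafold = "RNAfold") {
  function(sequence) {
    out <- system2(rnafold, args = c("--noPS"), input = sequence,
                   stdout = TRUE, stderr = FALSE)
    line <- out[length(out)]
    m <- stringr::str_match(line, "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)")
    if (is.na(m[1, 1])) abort("could not parse RNAfold output")
    list(structure = m[1, 2], mfe = as.numeric(m[1, 3]))
  }
}

#' Apply a single-base substitution to a sequence
#'
#' @param sequence RNA string.
#' @param hairpin_pos 0-based position within the sequence.
#' @param to_base Replacement RNA base; must differ from the current base.
#' @return The substituted sequence (the input is untouched).
#' @export
apply_substitution <- function(sequence, hairpin_pos, to_base) {
  sequence <- toupper(sequence)
  to_base <- toupper(to_base)
  n <- nchar(sequence)
  if (hairpin_pos < 0 || hairpin_pos >= n) {
    abort("hairpin_pos out of range")
  }
  if (!to_base %in% RNA_BASES) abort("to_base must be an RNA base")
  cur <- substr(sequence, hairpin_pos + 1, hairpin_pos + 1)
  if (cur == to_base) abort("substitution must change the base")
  paste0(substr(sequence, 1, hairpin_pos), to_base,
         substr(sequence, hairpin_pos + 2, n))
}

#' Relative MFE change for every mapped substitution
#'
#' Each substitution event is evaluated one at a time (simultaneous
#' substitutions in one hairpin are assumed unlikely): the full precursor
#' is folded with the ancestral (hairpin-reference) base and with the
#' mutated base, and the effect scored as
#' `rel_change = (mfe_mut - mfe_anc) / |mfe_anc|`, positive when the
#' mutated hairpin is less stable (destabilising). Multi-allelic SNPs yield
#' one record per alternate allele. Records whose ancestral fold has zero
#' energy carry an undefined relative change (`class = "undefined"`, NA
#' `rel_change`); records with `|rel_change| <= eps` are classed "neutral"
#' (no structural influence).
#'
#' @param mapped Mapped-SNP tibble from [map_snps()].
#' @param annotation A `mirna_annotation`.
#' @param engine,fold_fn,min_loop Passed to [fold_mfe()].
#' @param eps Neutrality threshold on `|rel_change|` (default 1e-9, exact
#'   zero detection under the integer-weight builtin engine).
#' @return Tibble (snp_id, precursor_id, hairpin_pos, from_base, to_base,
#'   mfe_anc, mfe_mut, rel_change, class) with class in destabilizing /
#'   stabilizing / neutral / undefined.
#' @export
delta_mfe_table <- function(mapped, annotation, engine = "builtin",
                            fold_fn = NULL, min_loop = 3, eps = 1e-9) {
  ev <- substitution_events(mapped)
  seqs <- setNames(annotation$precursors$sequence,
                   annotation$precursors$precursor_id)
  anc_cache <- new.env(parent = emptyenv())
  anc_mfe <- function(pid) {
    if (is.null(anc_cache[[pid]])) {
      anc_cache[[pid]] <- fold_mfe(seqs[[pid]], engine, fold_fn, min_loop)$mfe
    }
    anc_cache[[pid]]
  }
  n <- nrow(ev)
  mfe_anc <- numeric(n)
  mfe_mut <- numeric(n)
  for (i in seq_len(n)) {
    pid <- ev$precursor_id[i]
    mfe_anc[i] <- anc_mfe(pid)
    mut <- apply_substitution(seqs[[pid]], ev$hairpin_pos[i], ev$to_base[i])
    mfe_mut[i] <- fold_mfe(mut, engine, fold_fn, min_loop)$mfe
  }
  rel <- ifelse(mfe_anc == 0, NA_real_, (mfe_mut - mfe_anc) / abs(mfe_anc))
  cls <- dplyr::case_when(
    is.na(rel) ~ "undefined",
    abs(rel) <= eps ~ "neutral",
    rel > 0 ~ "destabilizing",
    TRUE ~ "stabilizing")
  tibble::tibble(snp_id = ev$snp_id, precursor_id = ev$precursor_id,
                 hairpin_pos = ev$hairpin_pos, from_base = ev$from_base,
                 to_base = ev$to_base, mfe_anc = mfe_anc, mfe_mut = mfe_mut,
                 rel_change = rel, class = cls)
}

#' Summary of structural influence of substitutions
#'
#' @param records Tibble from [delta_mfe_table()].
#' @return One-row tibble: totals per class and the fraction of defined
#'   records with no structural influence (`frac_neutral`).
#' @export
structure_summary <- function(records) {
  n <- nrow(records)
  n_undef <- sum(records$class == "undefined")
  n_def <- n - n_undef
  tibble::tibble(
    n = n,
    n_destabilizing = sum(records$class == "destabilizing"),
    n_stabilizing = sum(records$class == "stabilizing"),
    n_neutral = sum(records$class == "neutral"),
    n_undefined = n_undef,
    frac_neutral = if (n_def > 0) sum(records$class == "neutral") / n_def else NA_real_,
    frac_destabilizing = if (n_def > 0) sum(records$class == "destabilizing") / n_def else NA_real_,
    frac_stabilizing = if (n_def > 0) sum(records$class == "stabilizing") / n_def else NA_real_)
}

#' Write fold results in Vienna dot-bracket format
#'
#' One block per record: `>id`, sequence line, structure line with the
#' energy in parentheses.
#'
#' @param ids Character vector of record ids.
#' @param folds List of `fold_result` objects (same length).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dotbracket <- function(ids, folds, path) {
  stopifnot(length(ids) == length(folds))
  lines <- unlist(lapply(seq_along(ids), function(i) {
    f <- folds[[i]]
    c(paste0(">", ids[i]), f$sequence,
      sprintf("%s (%.2f)", f$structure, f$mfe))
  }))
  writeLines(lines, path)
  invisible(path)
}
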