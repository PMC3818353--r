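#' Monte-Carlo chi-square test for allele-frequency difference
#'
#' Pearson chi-square on the 2x2 allele-count table of two populations,
#' with the p-value estimated by Monte-Carlo resampling of tables with the
#' observed margins (for a 2x2 table this is a hypergeometric draw of the
#' first cell). The estimator is `(1 + #{replicate chi2 >= observed}) /
#' (reps + 1)`, so p is never 0. A zero row or column margin carries no
#' information: the statistic is 0 and p = 1.
#'
#' @param counts_a,counts_b Length-2 vectors `(ref_count, alt_count)`.
#' @param reps Number of Monte-Carlo replicates (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `chi2` and `p`.
#' @export
#' @examples
#' pair_chi2_mc(c(90, 10), c(10, 90), reps = 1000, seed = 1)
pair_chi2_mc <- function(counts_a, counts_b, reps = 10000, seed = NULL) {
  stopifnot(length(counts_a) == 2, length(counts_b) == 2, reps >= 1)
  if (any(c(counts_a, counts_b) < 0)) abort("allele counts must be >= 0")
  counts_a <- as.numeric(counts_a)
  counts_b <- as.numeric(counts_b)
  n1 <- sum(counts_a); n2 <- sum(counts_b)
  if (n1 == 0 || n2 == 0) abort("both populations need a positive total")
  c1 <- counts_a[1] + counts_b[1]
  c2 <- counts_a[2] + counts_b[2]
  if (c1 == 0 || c2 == 0) {
    return(list(chi2 = 0, p = 1))
  }
  N <- n1 + n2
  chi2_of <- function(n11) N * (N * n11 - n1 * c1)^2 / (n1 * n2 * c1 * c2)
  obs <- chi2_of(counts_a[1])
  if (!is.null(seed)) set.seed(seed)
  sim <- chi2_of(rhyper(reps, m = c1, n = c2, k = n1))
  p <- (1 + sum(sim >= obs - 1e-9)) / (reps + 1)
  list(chi2 = unname(obs), p = p)
}

#' Pairwise population-differentiation matrix
#'
#' For every pair of populations in the panel, tests each SNP with data in
#' both populations by [pair_chi2_mc()], adjusts that pair's p-values with
#' Benjamini-Hochberg FDR (the default family; `family = "global"` pools
#' all pairs), and counts SNPs with q below `alpha`. The result is a
#' symmetric populations-by-populations count matrix with a zero diagonal.
#'
#' @param panel Panel tibble (snp_id, population, ref_count, alt_count).
#' @param alpha FDR significance threshold (default 0.01).
#' @param reps Monte-Carlo replicates per SNP test.
#' @param seed Integer seed; the whole matrix is reproducible given it.
#' @param family FDR family: "pair" (default) or "global".
#' @return Object of class `pairwise_diff`: list with `matrix` (named
#'   square matrix of counts), `tests` (tibble snp_id, pop_a, pop_b, chi2,
#'   p, q), `alpha`, `reps`, `family`.
#' @export
diff_matrix <- function(panel, alpha = 0.01, reps = 10000, seed = 1,
                        family = c("pair", "global")) {
  family <- match.arg(family)
  stopifnot(alpha > 0, alpha < 1)
  pops <- sort(unique(panel$population))
  if (length(pops) < 2) abort("need at least 2 populations")
  set.seed(seed)
  panel <- dplyr::filter(panel, .data$ref_count + .data$alt_count > 0) |>
    dplyr::arrange(.data$population, .data$snp_id)
  tests <- list()
  for (i in seq_len(length(pops) - 1)) {
    for (j in seq(i + 1, length(pops))) {
      pa <- dplyr::filter(panel, .data$population == pops[i])
      pb <- dplyr::filter(panel, .data$population == pops[j])
      both <- dplyr::inner_join(pa, pb, by = "snp_id",
                                suffix = c("_a", "_b")) |>
        dplyr::arrange(.data$snp_id)
      if (nrow(both) == 0) next
      res <- purrr::map2(
        purrr::map2(both$ref_count_a, both$alt_count_a, c),
        purrr::map2(both$ref_count_b, both$alt_count_b, c),
        \(a, b) pair_chi2_mc(a, b, reps = reps))
      tests[[paste(pops[i], pops[j])]] <- tibble::tibble(
        snp_id = both$snp_id, pop_a = pops[i], pop_b = pops[j],
        chi2 = purrr::map_dbl(res, "chi2"), p = purrr::map_dbl(res, "p"))
    }
  }
  tests <- dplyr::bind_rows(tests)
  if (nrow(tests) > 0) {
    if (family == "pair") {
      tests <- tests |>
        dplyr::group_by(.data$pop_a, .data$pop_b) |>
        dplyr::mutate(q = bh_fdr(.data$p)) |>
        dplyr::ungroup()
    } else {
      tests$q <- bh_fdr(tests$p)
    }
  } else {
    tests$q <- numeric(0)
  }
  m <- matrix(0L, length(pops), length(pops), dimnames = list(pops, pops))
  if (nrow(tests) > 0) {
    sig <- tests |>
      dplyr::filter(.data$q < alpha) |>
      dplyr::count(.data$pop_a, .data$pop_b)
    for (r in seq_len(nrow(sig))) {
      m[sig$pop_a[r], sig$pop_b[r]] <- sig$n[r]
      m[sig$pop_b[r], sig$pop_a[r]] <- sig$n[r]
    }
  }
  structure(list(matrix = m, tests = tests, alpha = alpha, reps = reps,
                 family = family),
            class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, ...) {
  cat("Pairwise differentiated-SNP counts (q < ", x$alpha, ", ",
      x$reps, " MC reps, FDR family = ", x$family, ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' @export
tidy.pairwise_diff <- function(x, ...) x$tests

#' @export
glance.pairwise_diff <- function(x, ...) {
  tibble::tibble(n_populations = nrow(x$matrix),
                 n_tests = nrow(x$tests),
                 n_significant = sum(x$tests$q < x$alpha),
                 alpha = x$alpha, reps = x$reps, family = x$family)
}

#' Hierarchical clustering of populations from a differentiation matrix
#'
#' Agglomerative clustering of the matrix rows (Euclidean distance between
#' row profiles), average linkage (UPGMA) by default. Populations are
#' ordered lexicographically before clustering so ties break
#' deterministically. The dendrogram is returned as an `hclust`, a tidy
#' merge table, and a Newick string with branch lengths derived from merge
#' heights.
#'
#' @param mat Symmetric named count matrix (as in
#'   [diff_matrix()]`$matrix`).
#' @param linkage "average" (default), "single" or "complete".
#' @return Object of class `pop_dendrogram`: list(hclust, merges, newick,
#'   linkage).
#' @export
cluster_populations <- function(mat, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) ||
      !isTRUE(all.equal(mat, t(mat), check.attributes = FALSE))) {
    abort("differentiation matrix must be square and symmetric")
  }
  if (nrow(mat) < 2) abort("need at least 2 populations")
  ord <- order(rownames(mat))
  mat <- mat[ord, ord, drop = FALSE]
  hc <- hclust(dist(mat, method = "euclidean"), method = linkage)
  merges <- tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    left = merge_label(hc, hc$merge[, 1]),
    right = merge_label(hc, hc$merge[, 2]),
    height = hc$height)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, merges = merges, newick = newick,
                 linkage = linkage),
            class = "pop_dendrogram")
}

merge_label <- function(hc, idx) {
  vapply(idx, function(i) {
    if (i < 0) hc$labels[-i] else paste0("node_", i)
  }, character(1))
}

#' @export
print.pop_dendrogram <- function(x, ...) {
  cat("Population dendrogram (", x$linkage, " linkage)\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
tidy.pop_dendrogram <- function(x, ...) x$merges
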