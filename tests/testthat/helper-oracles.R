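# Independent brute-force oracles. These deliberately use different
# algorithms from the package paths they check.

oracle_pair_weight <- function(a, b) {
  key <- paste0(a, b)
  w <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
  if (key %in% names(w)) unname(w[key]) else 0
}

# Enumerate every non-crossing structure (as a list of pair index pairs)
# with minimum hairpin loop `min_loop`, and return the best total weight.
# Exponential; only for short sequences.
oracle_best_fold <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  enum <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- enum(i + 1, j)  # i unpaired
    for (k in seq(i + min_loop + 1, j)) {
      if (k > j) break
      if (oracle_pair_weight(s[i], s[k]) > 0) {
        inner <- enum(i + 1, k - 1)
        outer <- enum(k + 1, j)
        for (a in inner) for (b in outer) {
          out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
        }
      }
    }
    out
  }
  if (n < 2) return(0)
  structs <- enum(1, n)
  score <- vapply(structs, function(ps) {
    if (length(ps) == 0) return(0)
    sum(vapply(ps, function(p) oracle_pair_weight(s[p[1]], s[p[2]]),
               numeric(1)))
  }, numeric(1))
  -max(score)
}

# Upper-tail hypergeometric by explicit enumeration of all C(N, n) draws.
oracle_hypergeom_upper <- function(N, K, n, k) {
  if (n == 0 || k == 0) return(1)
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# Mann-Whitney exact p by label enumeration with the pair-counting U
# (number of (a, b) pairs with a < b, ties counting 1/2).
oracle_mw_exact <- function(a, b, tail) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(a, b)
  splits <- utils::combn(length(pool), na)
  u_all <- apply(splits, 2, function(ix) u_of(pool[ix], pool[-ix]))
  p_less <- mean(u_all <= u_obs + 1e-9)
  p_greater <- mean(u_all >= u_obs - 1e-9)
  switch(tail, less = p_less, greater = p_greater,
         two = min(1, 2 * min(p_less, p_greater)))
}

# All permutations of 1..n as a list (recursive, independent generator).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- oracle_perms(n - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# Spearman exact p by full permutation enumeration with textbook Pearson-
# on-ranks rho.
oracle_spearman_exact <- function(x, y, tail) {
  rx <- rank(x); ry <- rank(y)
  pear <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  rho_obs <- pear(rx, ry)
  rho_all <- vapply(oracle_perms(length(y)),
                    function(p) pear(rx, ry[p]), numeric(1))
  p_less <- mean(rho_all <= rho_obs + 1e-9)
  p_greater <- mean(rho_all >= rho_obs - 1e-9)
  switch(tail, less = p_less, greater = p_greater,
         two = min(1, 2 * min(p_less, p_greater)))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# dot-bracket structure validity + score recomputation
structure_score <- function(seq, db) {
  s <- strsplit(seq, "")[[1]]
  d <- strsplit(db, "")[[1]]
  stack <- integer(0)
  total <- 0
  min_loop_ok <- TRUE
  for (i in seq_along(d)) {
    if (d[i] == "(") stack <- c(stack, i)
    if (d[i] == ")") {
      if (length(stack) == 0) return(NULL)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      w <- oracle_pair_weight(s[j], s[i])
      if (w == 0) return(NULL)
      if (i - j - 1 < 3) min_loop_ok <- FALSE
      total <- total + w
    }
  }
  if (length(stack) > 0 || !min_loop_ok) return(NULL)
  -total
}

tiny_annotation <- function() {
  # two precursors, one on each strand, with one mature each
  s1 <- substr(paste(rep("ACGU", 22), collapse = ""), 1, 85)
  set.seed(42)
  s2 <- paste(sample(c("A", "C", "G", "U"), 85, replace = TRUE), collapse = "")
  pre <- tibble::tibble(
    precursor_id = c("pre1", "pre2"),
    name = c("pre1", "pre2"),
    chrom = c("chr1", "chr1"),
    start = c(1000L, 5000L), end = c(1085L, 5085L),
    strand = c("+", "-"),
    sequence = c(s1, s2))
  mat <- tibble::tibble(
    mature_id = c("mat1", "mat2"),
    precursor_id = c("pre1", "pre2"),
    offset = c(10L, 50L), length = c(22L, 22L))
  mirna_annotation(pre, mat)
}
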