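new_mirsnp_test <- function(method, statistic, p, tail, n_a, n_b,
                            estimate = NA_real_, extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p = unname(p), tail = tail, n_a = n_a, n_b = n_b,
                   estimate = unname(estimate)), extra),
            class = "mirsnp_test")
}

#' @export
print.mirsnp_test <- function(x, ...) {
  cat(x$method, " (tail = ", x$tail, ")\n", sep = "")
  cat("  statistic = ", format(x$statistic), ", p = ", format(x$p), "\n",
      sep = "")
  if (!is.na(x$estimate)) cat("  estimate = ", format(x$estimate), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mirsnp_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 estimate = x$estimate, p.value = x$p, tail = x$tail,
                 n_a = x$n_a, n_b = x$n_b)
}

#' @export
glance.mirsnp_test <- function(x, ...) tidy(x)

resolve_tail <- function(tail) {
  match.arg(tail, c("less", "greater", "two"))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Compares the location of two samples by ranks. For small samples (both
#' sizes <= 8) the p-value is exact, from a full enumeration of the rank
#' permutation distribution of the U statistic (ties handled through
#' midranks); for larger samples a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' The statistic is U for the first sample; `tail = "less"` asks whether
#' sample `a` is stochastically smaller than sample `b`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param tail "less", "greater" or "two".
#' @return A `mirsnp_test` (see [tidy()]): statistic U, p-value, tail.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6), tail = "less")
mann_whitney <- function(a, b, tail = "two") {
  tail <- resolve_tail(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  if (na <= 8 && nb <= 8) {
    # exact: every way of assigning the combined ranks to group a
    idx <- combn(na + nb, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_less <- mean(u_all <= u_obs + eps)
    p_greater <- mean(u_all >= u_obs - eps)
    p <- switch(tail, less = p_less, greater = p_greater,
                two = min(1, 2 * min(p_less, p_greater)))
  } else {
    mu <- na * nb / 2
    nties <- table(r)
    n <- na + nb
    sigma2 <- na * nb / 12 * (n + 1 - sum(nties^3 - nties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sd <- sqrt(sigma2)
      z_less <- (u_obs - mu + 0.5) / sd
      z_greater <- (u_obs - mu - 0.5) / sd
      p <- switch(tail,
                  less = pnorm(z_less),
                  greater = pnorm(z_greater, lower.tail = FALSE),
                  two = min(1, 2 * min(pnorm(z_less),
                                       pnorm(z_greater, lower.tail = FALSE))))
    }
  }
  new_mirsnp_test("Mann-Whitney rank-sum", u_obs, max(p, .Machine$double.xmin),
                  tail, na, nb)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' `tail = "less"` asks whether the mean of `a` is below the mean of `b`.
#' When both samples are constant: equal means give p = 1 by convention;
#' distinct means give the degenerate one-sided limit (0 or 1).
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param tail "less", "greater" or "two".
#' @return A `mirsnp_test`; `extra` fields carry group means, SEMs and df.
#' @export
welch_t <- function(a, b, tail = "two") {
  tail <- resolve_tail(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort("each sample needs >= 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      tstat <- 0; df <- na + nb - 2; p <- 1
    } else {
      tstat <- sign(ma - mb) * Inf; df <- na + nb - 2
      p <- switch(tail, less = as.numeric(ma > mb),
                  greater = as.numeric(ma < mb), two = 0)
      p <- max(p, .Machine$double.xmin)
    }
  } else {
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- switch(tail,
                less = pt(tstat, df),
                greater = pt(tstat, df, lower.tail = FALSE),
                two = 2 * pt(-abs(tstat), df))
    p <- max(min(p, 1), .Machine$double.xmin)
  }
  new_mirsnp_test("Welch t-test", tstat, p, tail, na, nb,
                  estimate = ma - mb,
                  extra = list(mean_a = ma, mean_b = mb,
                               sem_a = sqrt(va / na), sem_b = sqrt(vb / nb),
                               df = df))
}

#' Spearman rank correlation
#'
#' Tie-corrected rho (Pearson correlation of midranks). For n < 10 the
#' p-value is exact, by full enumeration of the n! rank permutations; for
#' n >= 10 a t approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y Paired numeric vectors, length >= 3, neither constant.
#' @param tail "two" (default), "less" (negative association) or "greater".
#' @return A `mirsnp_test`; `estimate` is rho.
#' @export
spearman_cor <- function(x, y, tail = "two") {
  tail <- resolve_tail(tail)
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("rho is undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 10) {
    perms <- all_permutations(n)
    # correlation of rx with every permutation of ry; the rank multiset is
    # permutation-invariant so only the cross-sum varies
    rperm <- matrix(ry[perms], nrow = n)
    rho_all <- (colSums(rx * rperm) - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    eps <- 1e-9
    p_less <- mean(rho_all <= rho + eps)
    p_greater <- mean(rho_all >= rho - eps)
    p <- switch(tail, less = p_less, greater = p_greater,
                two = min(1, 2 * min(p_less, p_greater)))
  } else {
    if (abs(rho) == 1) {
      p <- .Machine$double.xmin
      if ((tail == "less" && rho > 0) || (tail == "greater" && rho < 0)) p <- 1
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- switch(tail,
                  less = pt(tstat, n - 2),
                  greater = pt(tstat, n - 2, lower.tail = FALSE),
                  two = 2 * pt(-abs(tstat), n - 2))
    }
  }
  new_mirsnp_test("Spearman rank correlation", rho, max(p, .Machine$double.xmin),
                  tail, n, n, estimate = rho)
}

# matrix of all permutations of 1..n, one per column (n <= 9)
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  out <- matrix(1L, nrow = 1)
  for (k in 2:max(2, n)) {
    if (k > n) break
    prev <- out
    out <- matrix(0L, nrow = k, ncol = ncol(prev) * k)
    col <- 1L
    for (j in seq_len(ncol(prev))) {
      for (pos in seq_len(k)) {
        out[, col] <- append(prev[, j], k, after = pos - 1L)
        col <- col + 1L
      }
    }
  }
  if (n == 1) out <- matrix(1L, 1, 1)
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` items without replacement from a population
#' of `N` items of which `K` are successes. Exact.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Draws.
#' @param k Observed successes among the draws.
#' @return The exact tail probability.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 4)  # 5/210
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N) abort("K and n cannot exceed N")
  if (k > n || k > K) abort("impossible configuration: k exceeds n or K")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; q < 0.01 is the significance convention used by
#' the population-differentiation screen.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}
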