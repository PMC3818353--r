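interval_annotation <- function(df) {
  # df: precursor_id, chrom, start, end, strand; sequences are fillers
  df$name <- df$precursor_id
  df$sequence <- strrep("A", df$end - df$start)
  mirna_annotation(df, tibble::tibble(mature_id = character(),
                                      precursor_id = character(),
                                      offset = integer(), length = integer()))
}

test_that("conservation tiers follow the species-count cutoffs", {
  fam <- tibble::tibble(family = c("f10", "f9", "f2", "f1"),
                        precursor_id = c("a", "b", "c", "d"),
                        species_count = c(10L, 9L, 2L, 1L))
  tiers <- assign_tiers(fam)
  expect_equal(tiers$tier[match(c("f10", "f9", "f2", "f1"), tiers$family)],
               c("highly", "lowly", "lowly", "non"))
  expect_error(assign_tiers(tibble::tibble(family = "x", precursor_id = "a",
                                           species_count = 0L)), ">= 1")
})

test_that("familyless miRNAs default to non-conserved", {
  ann <- tiny_annotation()
  fam <- tibble::tibble(family = "famA", precursor_id = "pre1",
                        species_count = 12L)
  tiers <- mirna_tiers(ann, fam)
  expect_equal(tiers$tier[tiers$precursor_id == "pre1"], "highly")
  expect_equal(tiers$tier[tiers$precursor_id == "pre2"], "non")
})

test_that("cluster detection chains sub-threshold gaps on one strand", {
  ann <- interval_annotation(tibble::tibble(
    precursor_id = c("m1", "m2", "m3"),
    chrom = "chr1", strand = "+",
    start = c(1000L, 6100L, 21200L),
    end = c(1100L, 6200L, 21300L)))
  # gaps: 5000 and 15000
  cl <- detect_clusters(ann, 10000)
  expect_equal(cl$cluster_id[cl$precursor_id %in% c("m1", "m2")],
               rep(cl$cluster_id[cl$precursor_id == "m1"], 2))
  expect_true(is.na(cl$cluster_id[cl$precursor_id == "m3"]))

  # transitive chaining: gaps 9000 and 9000 form one cluster of three
  ann2 <- interval_annotation(tibble::tibble(
    precursor_id = c("m1", "m2", "m3"), chrom = "chr1", strand = "+",
    start = c(0L, 9100L, 18200L), end = c(100L, 9200L, 18300L)))
  cl2 <- detect_clusters(ann2, 10000)
  expect_equal(length(unique(cl2$cluster_id)), 1)
  expect_true(all(cl2$clustered))

  # identical interval on opposite strands never clusters
  ann3 <- interval_annotation(tibble::tibble(
    precursor_id = c("s", "as"), chrom = "chr1", strand = c("+", "-"),
    start = c(0L, 0L), end = c(100L, 100L)))
  expect_false(any(detect_clusters(ann3, 10000)$clustered))
})

test_that("cluster detection is order-invariant and monotone in the threshold", {
  set.seed(41)
  df <- tibble::tibble(
    precursor_id = sprintf("m%02d", 1:30),
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    strand = sample(c("+", "-"), 30, replace = TRUE),
    start = sample.int(500000, 30))
  df$end <- df$start + 100L
  ann_a <- interval_annotation(df)
  ann_b <- interval_annotation(df[sample(30), ])
  a <- dplyr::arrange(detect_clusters(ann_a, 10000), precursor_id)
  b <- dplyr::arrange(detect_clusters(ann_b, 10000), precursor_id)
  expect_equal(a$clustered, b$clustered)
  expect_equal(is.na(a$cluster_id), is.na(b$cluster_id))
  for (thr in c(1000, 5000, 10000, 20000, 50000)) {
    n_lo <- sum(detect_clusters(ann_a, thr)$clustered)
    n_hi <- sum(detect_clusters(ann_a, thr * 2)$clustered)
    expect_lte(n_lo, n_hi)
  }
})

test_that("flanking units carry gap-restricted variant counts", {
  ann <- interval_annotation(tibble::tibble(
    precursor_id = c("m1", "m2"), chrom = "chr1", strand = "+",
    start = c(100L, 700L), end = c(200L, 800L)))
  cl <- detect_clusters(ann, 10000)
  v <- tibble::tibble(snp_id = c("a", "b", "c", "d"),
                      chrom = "chr1", pos = c(250L, 400L, 650L, 150L),
                      ref = "A", alt = "G", vclass = "substitution",
                      validated = FALSE, ancestral = NA_character_)
  fl <- flanking_density(cl, v)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$n, 3L)  # the SNP inside m1 is not in the gap
  expect_equal(fl$L, 500L)
  expect_equal(fl$density, 0.006)

  # adjacent members emit no flanking unit
  ann2 <- interval_annotation(tibble::tibble(
    precursor_id = c("m1", "m2"), chrom = "chr1", strand = "+",
    start = c(100L, 200L), end = c(200L, 300L)))
  expect_equal(nrow(flanking_density(detect_clusters(ann2, 10000), v)), 0)
})

test_that("fragile-site overlap respects half-open intervals and classes", {
  ann <- interval_annotation(tibble::tibble(
    precursor_id = c("in1", "abut", "out"), chrom = "chr1", strand = "+",
    start = c(100L, 5000L, 90000L), end = c(185L, 5085L, 90085L)))
  sites <- tibble::tibble(name = "FRA1", chrom = "chr1", start = 150L,
                          end = 5000L, strand = "+", ftype = "common")
  lab <- fragile_overlap(ann, sites)
  expect_true(lab$in_common[lab$precursor_id == "in1"])
  expect_false(lab$in_any[lab$precursor_id == "abut"])  # start == site end
  expect_false(lab$in_any[lab$precursor_id == "out"])
})

test_that("enrichment counts and hypergeometric p match the toy example", {
  expect_equal(enrichment_test(5, 5, 4, 4), 5 / 210)
  expect_equal(enrichment_test(5, 5, 4, 0), 1)
  expect_equal(enrichment_test(5, 5, 0, 0), 1)
  expect_error(enrichment_test(5, 5, 4, 5), "impossible")

  # 10 miRNAs, 4 inside sites, 5 with >= 2 SNPs, 4 of them inside
  labels <- tibble::tibble(
    precursor_id = sprintf("m%02d", 1:10),
    in_any = c(rep(TRUE, 4), rep(FALSE, 6)),
    in_common = c(rep(TRUE, 4), rep(FALSE, 6)),
    in_rare = FALSE)
  mapped <- dplyr::bind_rows(lapply(c(1:4, 5), function(i) {
    tibble::tibble(snp_id = paste0("s", i, "_", 1:2),
                   precursor_id = sprintf("m%02d", i))
  }))
  enr <- fragile_enrichment(labels, mapped)
  row <- enr[enr$site_class == "any", ]
  expect_equal(c(row$n_in, row$n_out, row$n_multi, row$k_overlap),
               c(4L, 6L, 5L, 4L))
  expect_equal(row$p, hypergeom_upper_tail(10, 4, 5, 4))
})

test_that("enrichment test equals draw enumeration and is monotone in k", {
  set.seed(51)
  for (case in 1:30) {
    N <- sample(6:20, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper_tail(N, K, n, k),
                 oracle_hypergeom_upper(N, K, n, k),
                 tolerance = 1e-12, info = paste(N, K, n, k))
  }
  p_prev <- Inf
  for (k in 0:4) {
    p <- hypergeom_upper_tail(12, 6, 4, k)
    expect_lte(p, p_prev)
    p_prev <- p
  }
})

test_that("genic context is intersection-based and defaults to intergenic", {
  ann <- interval_annotation(tibble::tibble(
    precursor_id = c("inside", "outside"), chrom = "chr1", strand = "+",
    start = c(1000L, 50000L), end = c(1085L, 50085L)))
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 500L, end = 20000L)
  ctx <- genic_context(ann, genes)
  expect_equal(ctx$context[ctx$precursor_id == "inside"], "intragenic")
  expect_equal(ctx$context[ctx$precursor_id == "outside"], "intergenic")
  empty <- genic_context(ann, genes[0, ])
  expect_true(all(empty$context == "intergenic"))
})

test_that("clustered plus individual miRNAs partition the annotation", {
  set.seed(61)
  df <- tibble::tibble(
    precursor_id = sprintf("m%02d", 1:40),
    chrom = sample(c("chr1", "chr2", "chr3"), 40, replace = TRUE),
    strand = sample(c("+", "-"), 40, replace = TRUE),
    start = sample.int(300000, 40))
  df$end <- df$start + 90L
  ann <- interval_annotation(df)
  cl <- detect_clusters(ann, 10000)
  expect_setequal(cl$precursor_id, df$precursor_id)
  spans <- cluster_spans(cl)
  expect_true(all(spans$n_members >= 2))
  # clusters are disjoint: members assigned to exactly one cluster
  expect_equal(sum(spans$n_members), sum(cl$clustered))
})
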