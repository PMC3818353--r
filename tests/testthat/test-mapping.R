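make_variants <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(snp_id = r$id %||% paste0("rs", i), chrom = r$chrom,
                   pos = as.integer(r$pos), ref = r$ref, alt = r$alt,
                   vclass = mirsnp:::classify_vclass(r$ref, r$alt),
                   validated = FALSE, ancestral = NA_character_)
  }))
}

test_that("plus-strand variants map to the 5'-offset of the hairpin", {
  ann <- tiny_annotation()
  seq1 <- ann$precursors$sequence[1]
  ref12 <- rna_to_dna(substr(seq1, 13, 13))
  v <- make_variants(list(chrom = "chr1", pos = 1012, ref = ref12, alt = "G"))
  m <- map_snps(v, ann)
  expect_equal(m$hairpin_pos, 12L)
  expect_equal(m$anc_base, substr(seq1, 13, 13))
  expect_false(m$ref_mismatch)
})

test_that("minus-strand mapping reverse-complements position and alleles", {
  # hairpin sense sequence starts with U; the forward-strand base under
  # hairpin position 0 is then A (pos = end - 1)
  s <- paste0("U", substr(tiny_annotation()$precursors$sequence[2], 2, 85))
  pre <- tibble::tibble(precursor_id = "preM", name = "preM", chrom = "chr3",
                        start = 1000L, end = 1085L, strand = "-",
                        sequence = s)
  ann <- mirna_annotation(pre, tibble::tibble(
    mature_id = character(), precursor_id = character(),
    offset = integer(), length = integer()))
  v <- make_variants(list(chrom = "chr3", pos = 1084, ref = "A", alt = "G"))
  m <- map_snps(v, ann)
  expect_equal(m$hairpin_pos, 0L)
  expect_equal(m$anc_base, "U")
  expect_equal(m$mut_bases, "C")
  expect_false(m$ref_mismatch)
})

test_that("strand property: mapping is invariant under genome reverse-complement", {
  set.seed(21)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  G <- 10000L
  for (case in 1:25) {
    L <- sample(60:90, 1)
    s0 <- sample(0:(G - L - 1), 1)
    seq_sense <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                       collapse = "")
    hp <- sample(0:(L - 1), 1)
    # forward annotation on + strand
    ann_f <- mirna_annotation(
      tibble::tibble(precursor_id = "p", name = "p", chrom = "c",
                     start = s0, end = s0 + L, strand = "+",
                     sequence = seq_sense),
      tibble::tibble(mature_id = "m", precursor_id = "p", offset = 5L,
                     length = 22L))
    ref_f <- rna_to_dna(substr(seq_sense, hp + 1, hp + 1))
    alt_f <- setdiff(c("A", "C", "G", "T"), ref_f)[sample(3, 1)]
    v_f <- make_variants(list(chrom = "c", pos = s0 + hp, ref = ref_f,
                              alt = alt_f))
    # the same locus after reverse-complementing the genome
    ann_r <- mirna_annotation(
      tibble::tibble(precursor_id = "p", name = "p", chrom = "c",
                     start = G - (s0 + L), end = G - s0, strand = "-",
                     sequence = seq_sense),
      tibble::tibble(mature_id = "m", precursor_id = "p", offset = 5L,
                     length = 22L))
    v_r <- make_variants(list(chrom = "c", pos = G - 1 - (s0 + hp),
                              ref = unname(comp[ref_f]),
                              alt = unname(comp[alt_f])))
    m_f <- map_snps(v_f, ann_f)
    m_r <- map_snps(v_r, ann_r)
    cols <- c("hairpin_pos", "anc_base", "mut_bases", "in_mature", "in_seed")
    expect_equal(m_f[cols], m_r[cols])
  }
})

test_that("seed occupancy covers mature positions 2-8 exactly", {
  ann <- tiny_annotation()  # mature mat1 at offset 10, length 22 on pre1
  seq1 <- ann$precursors$sequence[1]
  for (hp in 8:33) {
    ref <- rna_to_dna(substr(seq1, hp + 1, hp + 1))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    m <- map_snps(make_variants(list(chrom = "chr1", pos = 1000 + hp,
                                     ref = ref, alt = alt)), ann)
    in_mature <- hp >= 10 && hp <= 31
    in_seed <- hp >= 11 && hp <= 17
    expect_equal(m$in_mature != "", in_mature, info = hp)
    expect_equal(m$in_seed != "", in_seed, info = hp)
  }
})

test_that("reference mismatches are flagged, kept for counting, excluded from events", {
  ann <- tiny_annotation()
  seq1 <- ann$precursors$sequence[1]
  good_ref <- rna_to_dna(substr(seq1, 1, 1))
  bad_ref <- setdiff(c("A", "C", "G", "T"), good_ref)[1]
  v <- make_variants(list(chrom = "chr1", pos = 1000, ref = bad_ref, alt = good_ref))
  expect_warning(m <- map_snps(v, ann), "disagree")
  expect_true(m$ref_mismatch)
  expect_equal(nrow(substitution_events(m)), 0)
  d <- region_densities(m, ann)
  expect_equal(d$n[d$region == "precursor" & d$unit_id == "pre1"], 1L)
})

test_that("substitution classification follows the purine/pyrimidine rule", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("G", "C"), "transversion")
  types <- expand.grid(f = c("A", "C", "G", "U"), t = c("A", "C", "G", "U"),
                       stringsAsFactors = FALSE)
  types <- types[types$f != types$t, ]
  k <- classify_substitution(types$f, types$t)
  expect_equal(length(k), 12)
  expect_equal(sum(k == "transition"), 4)
  expect_error(classify_substitution("A", "A"), "different")
  expect_error(classify_substitution("A", "T"), "RNA")
})

test_that("snp_density is n/L and rejects bad lengths", {
  expect_equal(snp_density(2, 100), 0.02)
  expect_equal(snp_density(0, 85), 0)
  expect_equal(snp_density(17, 100), 0.17)
  expect_error(snp_density(1, 0), "positive")
})

test_that("density counts distinct SNP ids and the histogram bins precursors", {
  ann <- tiny_annotation()
  seq1 <- ann$precursors$sequence[1]
  ref_at <- function(hp) rna_to_dna(substr(seq1, hp + 1, hp + 1))
  alt_at <- function(hp) setdiff(c("A", "C", "G", "T"), ref_at(hp))[1:2]
  # 3 distinct SNPs on pre1, one of them bi-allelic
  v <- make_variants(
    list(id = "s1", chrom = "chr1", pos = 1002, ref = ref_at(2),
         alt = paste(alt_at(2), collapse = ",")),
    list(id = "s2", chrom = "chr1", pos = 1020, ref = ref_at(20), alt = alt_at(20)[1]),
    list(id = "s3", chrom = "chr1", pos = 1050, ref = ref_at(50), alt = alt_at(50)[1]))
  m <- map_snps(v, ann)
  d <- region_densities(m, ann)
  expect_equal(d$n[d$region == "precursor" & d$unit_id == "pre1"], 3L)
  expect_equal(d$density[d$region == "precursor" & d$unit_id == "pre1"], 3 / 85)
  expect_equal(d$L[d$region == "seed"], c(7L, 7L))

  h <- snp_count_histogram(m, ann)
  expect_equal(h$n_precursors[h$n_snps == 0], 1L)  # pre2 has none
  expect_equal(h$n_precursors[h$n_snps == 3], 1L)
})

test_that("region densities agree with a brute-force position scan", {
  set.seed(31)
  for (case in 1:20) {
    L <- sample(60:100, 1)
    seqs <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                  collapse = "")
    off <- sample(0:(L - 30), 1)
    ann <- mirna_annotation(
      tibble::tibble(precursor_id = "p", name = "p", chrom = "c",
                     start = 500L, end = 500L + L, strand = "+",
                     sequence = seqs),
      tibble::tibble(mature_id = "m", precursor_id = "p",
                     offset = off, length = 22L))
    positions <- sort(sample(0:(L - 1), sample(1:10, 1)))
    v <- dplyr::bind_rows(lapply(positions, function(hp) {
      ref <- rna_to_dna(substr(seqs, hp + 1, hp + 1))
      make_variants(list(id = paste0("s", hp), chrom = "c", pos = 500 + hp,
                         ref = ref,
                         alt = setdiff(c("A", "C", "G", "T"), ref)[1]))
    }))
    m <- map_snps(v, ann)
    d <- region_densities(m, ann)
    # oracle: indicator scan over unit positions
    n_mat <- sum(positions >= off & positions < off + 22)
    n_seed <- sum(positions >= off + 1 & positions <= off + 7)
    expect_equal(d$n[d$region == "precursor"], length(positions))
    expect_equal(d$n[d$region == "mature"], n_mat)
    expect_equal(d$n[d$region == "seed"], n_seed)
  }
})

test_that("substitution table propagates region flags and preserves count order", {
  ann <- tiny_annotation()
  seq1 <- ann$precursors$sequence[1]
  ref_at <- function(hp) rna_to_dna(substr(seq1, hp + 1, hp + 1))
  pick <- function(hp) {
    # a transition alternate for determinism
    c(A = "G", G = "A", C = "T", T = "C")[[ref_at(hp)]]
  }
  v <- make_variants(
    list(id = "s_seed", chrom = "chr1", pos = 1012, ref = ref_at(12), alt = pick(12)),
    list(id = "s_mat", chrom = "chr1", pos = 1030, ref = ref_at(30), alt = pick(30)),
    list(id = "s_out", chrom = "chr1", pos = 1050, ref = ref_at(50), alt = pick(50)))
  m <- map_snps(v, ann)
  tbl <- substitution_table(m)
  per_type <- tbl[!is.na(tbl$from_base), ]
  expect_true(all(per_type$seed <= per_type$mature))
  expect_true(all(per_type$mature <= per_type$precursor))
  expect_equal(tbl$precursor[tbl$substitution == "total"], 3)
  expect_equal(tbl$mature[tbl$substitution == "total"], 2)
  expect_equal(tbl$seed[tbl$substitution == "total"], 1)
  # subtotal rows really are the sums of their member rows
  k <- classify_substitution(per_type$from_base, per_type$to_base)
  expect_equal(tbl$precursor[tbl$substitution == "subtotal of transition"],
               sum(per_type$precursor[k == "transition"]))
})
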