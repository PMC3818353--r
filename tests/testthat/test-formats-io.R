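write_toy_gff_fasta <- function(dir, mature_bad = FALSE) {
  gff <- file.path(dir, "ann.gff3")
  fa <- file.path(dir, "ann.fa")
  lines <- c(
    "##gff-version 3",
    "chr1\tsrc\tmiRNA_primary_transcript\t1001\t1085\t.\t+\t.\tID=preA;Name=preA",
    "chr1\tsrc\tmiRNA\t1011\t1032\t.\t+\t.\tID=matA;Derives_from=preA",
    "chr2\tsrc\tmiRNA_primary_transcript\t2001\t2080\t.\t-\t.\tID=preB;Name=preB",
    "chr2\tsrc\tmiRNA\t2011\t2032\t.\t-\t.\tID=matB;Derives_from=preB")
  if (mature_bad) {
    lines <- c(lines,
      "chr1\tsrc\tmiRNA\t1071\t1092\t.\t+\t.\tID=matBad;Derives_from=preA")
  }
  writeLines(lines, gff)
  set.seed(11)
  seqA <- paste(sample(c("A", "C", "G", "T"), 85, replace = TRUE), collapse = "")
  seqB <- paste(sample(c("A", "C", "G", "U"), 80, replace = TRUE), collapse = "")
  writeLines(c(">preA", seqA, ">preB", seqB), fa)
  list(gff = gff, fa = fa, seqA = seqA, seqB = seqB)
}

test_that("GFF3/FASTA reading converts coordinates and alphabet at the boundary", {
  dir <- withr::local_tempdir()
  fx <- write_toy_gff_fasta(dir)
  ann <- read_mirna_annotation(fx$gff, fx$fa)

  a <- ann$precursors[ann$precursors$precursor_id == "preA", ]
  expect_equal(a$start, 1000L)   # 1-based inclusive 1001 -> 0-based 1000
  expect_equal(a$end, 1085L)
  expect_equal(a$length, 85L)
  expect_equal(a$sequence, dna_to_rna(fx$seqA))  # T -> U
  expect_true(all(grepl("^[ACGU]+$", ann$precursors$sequence)))

  # plus-strand mature offset; minus-strand offset measured from hairpin 5' end
  mA <- ann$matures[ann$matures$mature_id == "matA", ]
  expect_equal(mA$offset, 10L)
  expect_equal(mA$length, 22L)
  mB <- ann$matures[ann$matures$mature_id == "matB", ]
  expect_equal(mB$offset, 2080L - 2032L)
})

test_that("matures that overflow their precursor are dropped with a warning", {
  dir <- withr::local_tempdir()
  fx <- write_toy_gff_fasta(dir, mature_bad = TRUE)
  expect_warning(ann <- read_mirna_annotation(fx$gff, fx$fa), "matBad")
  expect_false("matBad" %in% ann$matures$mature_id)
  expect_true("matA" %in% ann$matures$mature_id)
})

test_that("GFF3 ids missing from the FASTA are an error", {
  dir <- withr::local_tempdir()
  fx <- write_toy_gff_fasta(dir)
  writeLines(c(">preA", fx$seqA), file.path(dir, "short.fa"))
  expect_error(read_mirna_annotation(fx$gff, file.path(dir, "short.fa")),
               "preB")
})

test_that("annotation round-trips through GFF3 + FASTA", {
  dir <- withr::local_tempdir()
  ann <- tiny_annotation()
  write_mirna_annotation(ann, file.path(dir, "rt.gff3"), file.path(dir, "rt.fa"))
  back <- read_mirna_annotation(file.path(dir, "rt.gff3"), file.path(dir, "rt.fa"))
  expect_equal(back$precursors[, names(ann$precursors)], ann$precursors)
  expect_equal(dplyr::arrange(back$matures, mature_id),
               dplyr::arrange(ann$matures, mature_id))
})

test_that("VCF positions, classes and INFO flags are normalized on read", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "v.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1085\trs1\tA\tG\t.\t.\tANC=A;VLD",
    "chr1\t1100\trs2\tA\tAG\t.\t.\t.",
    "chr1\t1200\trs3\tC\tG,T\t.\t.\t.",
    "chr1\t1300\trs4\tN\tG\t.\t.\t."), vcf)
  v <- read_variants(vcf, "vcf")
  expect_equal(v$pos, c(1084L, 1099L, 1199L, 1299L))  # 1-based -> 0-based
  expect_equal(v$vclass, c("substitution", "indel", "substitution", "other"))
  expect_equal(v$alt[3], "G,T")  # multi-allelic stays one record
  expect_true(v$validated[1])
  expect_equal(v$ancestral[1], "A")
  expect_true(is.na(v$ancestral[2]))
})

test_that("malformed variant lines error with their line number", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "bad.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\trs1\tA\tG\t.\t.\t.",
               "chr1\tnotanumber\trs2\tA\tG\t.\t.\t."), vcf)
  expect_error(read_variants(vcf, "vcf"), "line 4")
  writeLines(c("chr1\t100"), file.path(dir, "short.vcf"))
  expect_error(read_variants(file.path(dir, "short.vcf"), "vcf"), "line 1")
})

test_that("variant tables round-trip through both dialects", {
  dir <- withr::local_tempdir()
  v <- tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"), chrom = c("chr1", "chr1", "chr2"),
    pos = c(99L, 149L, 0L), ref = c("A", "C", "G"),
    alt = c("G", "C,T", "GA"),
    vclass = c("substitution", "substitution", "indel"),
    validated = c(TRUE, FALSE, FALSE),
    ancestral = c("A", NA, NA))
  for (d in c("vcf", "tsv")) {
    f <- file.path(dir, paste0("x.", d))
    write_variants(v, f, d)
    expect_equal(read_variants(f, d), v, info = d)
  }
})

test_that("panel frequencies convert to allele counts and invalid rows error", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "panel.tsv")
  writeLines(c("#snp_id\tpopulation\tfreq\tn",
               "rs1\tCEU\t0.25\t50",
               "rs1\tYRI\t0\t10"), f)
  p <- read_panel(f)
  expect_equal(p$alt_count, c(25L, 0L))
  expect_equal(p$ref_count, c(75L, 20L))

  writeLines(c("#snp_id\tpopulation\tfreq\tn", "rs1\tCEU\t1.25\t50"), f)
  expect_error(read_panel(f), "outside")
  writeLines(c("#snp_id\tpopulation\tfreq", "rs1\tCEU\t0.25"), f)
  expect_error(read_panel(f), "sample size")

  # direct counts pass through unchanged; duplicate cells are rejected
  writeLines(c("#snp_id\tpopulation\tref_count\talt_count",
               "rs1\tCEU\t30\t70"), f)
  expect_equal(read_panel(f)$ref_count, 30L)
  writeLines(c("#snp_id\tpopulation\tref_count\talt_count",
               "rs1\tCEU\t30\t70", "rs1\tCEU\t1\t2"), f)
  expect_error(read_panel(f), "duplicate")
})

test_that("fragile sites resolve from coordinates or cytoband names", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "fs.tsv")
  writeLines(c("#name\tftype\tchrom\tstart\tend",
               "FRA1\tcommon\tchr1\t1001\t5000"), f)
  fs <- read_fragile_sites(f)
  expect_equal(fs$start, 1000L)
  expect_equal(fs$end, 5000L)
  expect_equal(fs$strand, "+")

  cyto <- read_cytobands(system.file("extdata", "cytobands_toy.tsv",
                                     package = "mirsnp"))
  writeLines(c("#name\tftype\tcytoband", "FRA2\trare\tchr1q1"), f)
  fs2 <- read_fragile_sites(f, cytobands = cyto)
  expect_equal(fs2$chrom, "chr1")
  expect_equal(fs2$start, 1500000L)
  writeLines(c("#name\tftype\tcytoband", "FRA3\trare\tnope"), f)
  expect_error(read_fragile_sites(f, cytobands = cyto), "unresolved")
  writeLines(c("#name\tftype\tchrom\tstart\tend",
               "FRA1\tweird\tchr1\t1001\t5000"), f)
  expect_error(read_fragile_sites(f), "common")
})

test_that("family tables expand to one row per member and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "fam.tsv")
  fam <- tibble::tibble(family = c("let-7", "let-7", "mir-1"),
                        precursor_id = c("a", "b", "c"),
                        species_count = c(31L, 31L, 5L))
  write_families(fam, f)
  expect_equal(dplyr::arrange(read_families(f), precursor_id),
               dplyr::arrange(fam, precursor_id))
})
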