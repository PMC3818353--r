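#' Configuration for the synthetic input generator
#'
#' Bundles every knob of the synthetic study system: a toy genome of
#' hairpin-bearing chromosomes, planted SNP-rate structure (seed < mature <
#' precursor, conserved < non-conserved, clustered < individual, a
#' multi-SNP boost inside common fragile sites), a planted negative
#' dependence between SNP burden and disease-association counts, and a
#' Balding-Nichols allele-frequency panel with a block of differentiated
#' SNPs confined to one designated population pair. Defaults are documented
#' constants chosen so a full bundle emulates the qualitative structure of
#' the human miRNA SNP landscape at desk scale; they are not claims about
#' human biology.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param n_mirnas Number of precursors (default 2000).
#' @param n_chromosomes,chrom_length_bp Toy genome shape.
#' @param precursor_length_range Hairpin length range in nt.
#' @param frac_antisense_pairs Fraction of precursors duplicated as a
#'   sense/antisense partner on the opposite strand of the same interval.
#' @param frac_familyless Fraction of miRNAs carrying no family label.
#' @param tier_probs Probabilities of a family being non / lowly / highly
#'   conserved (species count 1, 2-9, >= 10).
#' @param cluster_fraction Target fraction of miRNAs in genomic clusters.
#' @param cluster_size_range Cluster sizes (members).
#' @param within_cluster_gap_bp,between_unit_gap_bp Gap ranges (bp) inside
#'   clusters and between placement units.
#' @param n_fragile_sites,fragile_common_frac,fragile_length_bp Fragile-site
#'   count, common fraction and length range.
#' @param background_rate Per-bp SNP rate in an unconstrained precursor.
#' @param tier_multipliers Named rate multipliers (highly, lowly, non).
#' @param region_multipliers Named rate multipliers (mature, seed).
#' @param cluster_member_multiplier Rate multiplier for clustered miRNAs.
#' @param fragile_boost Rate boost for precursors inside common fragile
#'   sites (plants the multi-SNP enrichment).
#' @param indel_fraction,multiallelic_fraction,validated_fraction,ts_tv_odds
#'   Variant composition knobs (transition:transversion odds default 2).
#' @param n_genes,gene_length_bp Protein-coding gene intervals.
#' @param n_qtls,qtl_length_bp QTL intervals (placed independently of SNP
#'   rate, so the QTL-burden correlation is null by construction).
#' @param disease_lambda,disease_beta Disease counts are
#'   Poisson(lambda * exp(-beta * snp_count)); beta > 0 plants the negative
#'   correlation.
#' @param populations Population labels for the allele panel.
#' @param bn_f Balding-Nichols differentiation coefficient F in (0, 1).
#' @param n_panel_snps Panel size (SNPs with frequency data).
#' @param n_diff_snps Planted differentiated SNPs (data confined to the
#'   first two populations, lexicographically).
#' @param diff_freqs Planted frequencies for the designated pair.
#' @param diploid_n Diploid sample size per population (2N chromosomes).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_mirnas = 2000,
                       n_chromosomes = 10,
                       chrom_length_bp = 6e6,
                       precursor_length_range = c(60, 120),
                       frac_antisense_pairs = 0.005,
                       frac_familyless = 0.1,
                       tier_probs = c(non = 0.35, lowly = 0.45, highly = 0.20),
                       cluster_fraction = 0.2,
                       cluster_size_range = c(2, 6),
                       within_cluster_gap_bp = c(200, 8000),
                       between_unit_gap_bp = c(15000, 40000),
                       n_fragile_sites = 24,
                       fragile_common_frac = 0.75,
                       fragile_length_bp = c(100000, 400000),
                       background_rate = 0.02,
                       tier_multipliers = c(highly = 0.4, lowly = 0.7, non = 1.0),
                       region_multipliers = c(mature = 0.5, seed = 0.25),
                       cluster_member_multiplier = 0.5,
                       fragile_boost = 3,
                       indel_fraction = 0.06,
                       multiallelic_fraction = 0.03,
                       validated_fraction = 0.35,
                       ts_tv_odds = 2,
                       n_genes = 400,
                       gene_length_bp = c(10000, 200000),
                       n_qtls = 200,
                       qtl_length_bp = c(50000, 300000),
                       disease_lambda = 3,
                       disease_beta = 0.8,
                       populations = c("AFR", "AMR", "ASN", "EUR"),
                       bn_f = 0.001,
                       n_panel_snps = 120,
                       n_diff_snps = 20,
                       diff_freqs = c(0.9, 0.1),
                       diploid_n = 100) {
  cfg <- as.list(environment())
  stopifnot(cfg$background_rate >= 0, all(cfg$tier_multipliers > 0),
            all(cfg$region_multipliers > 0), cfg$fragile_boost > 0,
            cfg$bn_f > 0, cfg$bn_f < 1, length(cfg$populations) >= 2,
            cfg$n_diff_snps <= cfg$n_panel_snps)
  structure(cfg, class = "sim_config")
}

runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

rand_rna <- function(n, gc = 0.55) {
  paste(sample(RNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

hairpin_sequence <- function(L, mismatch = 0.1) {
  loop0 <- sample(6:10, 1)
  arm <- (L - loop0) %/% 2
  loop <- L - 2 * arm
  arm5 <- rand_rna(arm)
  arm3 <- strsplit(revcomp(arm5, "rna"), "")[[1]]
  flip <- runif(arm) < mismatch
  arm3[flip] <- sample(RNA_BASES, sum(flip), replace = TRUE)
  paste0(arm5, rand_rna(loop, gc = 0.4), paste(arm3, collapse = ""))
}

#' Simulate the annotation side of a synthetic bundle
#'
#' Places precursors (clustered subsets with sub-threshold gaps, everything
#' else far apart), draws hairpin-friendly sequences (complementary arms
#' around a loop, so folding baselines are non-degenerate), defines 5p/3p
#' matures, and generates family, fragile-site, gene and QTL tables.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List: `annotation` (a `mirna_annotation`), `families`,
#'   `fragile_sites`, `genes`, `qtls` tibbles, and `placement` (per-miRNA
#'   truth: tier, clustered flag, fragile/boost membership).
#' @export
simulate_annotation <- function(config) {
  set.seed(child_seed(config$seed, "annotation"))
  n <- config$n_mirnas
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  # placement units: clusters of >= 2 plus singletons
  target_clustered <- round(config$cluster_fraction * n)
  sizes <- integer(0)
  while (sum(sizes) < target_clustered) {
    sizes <- c(sizes, runif_int(1, config$cluster_size_range))
  }
  n_clustered <- sum(sizes)
  if (n_clustered > n) abort("cluster fraction incompatible with n_mirnas")
  units <- c(as.list(sizes), as.list(rep(1L, n - n_clustered)))
  units <- sample(units)
  unit_chrom <- rep_len(seq_along(chroms), length(units))

  rows <- vector("list", length(units))
  cursor <- setNames(runif_int(length(chroms), c(20000, 60000)), chroms)
  idx <- 0L
  for (u in seq_along(units)) {
    k <- units[[u]]
    ch <- chroms[unit_chrom[u]]
    strand <- sample(c("+", "-"), 1)
    lens <- runif_int(k, config$precursor_length_range)
    starts <- integer(k)
    pos <- cursor[ch]
    for (m in seq_len(k)) {
      starts[m] <- pos
      pos <- pos + lens[m] +
        if (m < k) runif_int(1, config$within_cluster_gap_bp) else 0L
    }
    cursor[ch] <- pos + runif_int(1, config$between_unit_gap_bp)
    if (cursor[ch] > config$chrom_length_bp) {
      abort("infeasible packing: too many miRNAs for the genome size")
    }
    rows[[u]] <- tibble::tibble(
      chrom = ch, strand = strand, start = starts, length = lens,
      unit = u, in_cluster = k >= 2)
    idx <- idx + k
  }
  pre <- dplyr::bind_rows(rows)
  pre$end <- pre$start + pre$length
  pre$precursor_id <- sprintf("mir-%04d", seq_len(nrow(pre)))
  pre$name <- pre$precursor_id
  pre$sequence <- vapply(pre$length, hairpin_sequence, character(1))

  # optional sense/antisense partners: same interval, opposite strand
  n_anti <- round(config$frac_antisense_pairs * n)
  if (n_anti > 0) {
    singles <- which(!pre$in_cluster)
    take <- sample(singles, min(n_anti, length(singles)))
    anti <- pre[take, ]
    anti$strand <- ifelse(anti$strand == "+", "-", "+")
    anti$precursor_id <- paste0(anti$precursor_id, "-as")
    anti$name <- anti$precursor_id
    anti$sequence <- revcomp(anti$sequence, "rna")
    pre <- dplyr::bind_rows(pre, anti)
  }

  matures <- purrr::map_dfr(seq_len(nrow(pre)), function(i) {
    L <- pre$length[i]
    l5 <- sample(20:23, 1); o5 <- sample(1:4, 1)
    l3 <- sample(20:23, 1); o3 <- L - l3 - sample(1:4, 1)
    tibble::tibble(
      mature_id = paste0(pre$precursor_id[i], c("-5p", "-3p")),
      precursor_id = pre$precursor_id[i],
      offset = as.integer(c(o5, o3)), length = as.integer(c(l5, l3)))
  })

  ann <- mirna_annotation(
    pre[, c("precursor_id", "name", "chrom", "start", "end", "strand",
            "sequence")],
    matures)

  # families and conservation tiers
  n_fam <- max(1L, nrow(pre) %/% 3L)
  fam_species <- vapply(seq_len(n_fam), function(i) {
    tier <- sample(names(config$tier_probs), 1, prob = config$tier_probs)
    switch(tier, non = 1L, lowly = sample(2:9, 1), highly = sample(10:40, 1))
  }, integer(1))
  has_family <- runif(nrow(pre)) >= config$frac_familyless
  fam_of <- ifelse(has_family, sample(n_fam, nrow(pre), replace = TRUE), NA)
  families <- tibble::tibble(
    family = sprintf("mir-fam-%03d", fam_of[has_family]),
    precursor_id = pre$precursor_id[has_family],
    species_count = fam_species[fam_of[has_family]])

  # fragile sites
  fr_chrom <- sample(chroms, config$n_fragile_sites, replace = TRUE)
  fr_len <- runif_int(config$n_fragile_sites, config$fragile_length_bp)
  fr_start <- as.integer(floor(runif(config$n_fragile_sites) *
                               (config$chrom_length_bp - fr_len)))
  n_common <- round(config$fragile_common_frac * config$n_fragile_sites)
  fragile_sites <- tibble::tibble(
    name = sprintf("FRA%02d", seq_len(config$n_fragile_sites)),
    chrom = fr_chrom, start = fr_start, end = fr_start + fr_len,
    strand = "+",
    ftype = c(rep("common", n_common),
              rep("rare", config$n_fragile_sites - n_common)))

  rand_intervals <- function(n, len_range, prefix) {
    len <- runif_int(n, len_range)
    ch <- sample(chroms, n, replace = TRUE)
    st <- as.integer(floor(runif(n) * (config$chrom_length_bp - len)))
    tibble::tibble(id = sprintf("%s_%03d", prefix, seq_len(n)), chrom = ch,
                   start = st, end = st + len)
  }
  genes <- rand_intervals(config$n_genes, config$gene_length_bp, "gene")
  names(genes)[1] <- "gene_id"
  qtls <- rand_intervals(config$n_qtls, config$qtl_length_bp, "qtl")
  names(qtls)[1] <- "qtl_id"
  qtls$trait <- sample(sprintf("trait_%02d", 1:39), nrow(qtls), replace = TRUE)
  qtls <- qtls[, c("qtl_id", "trait", "chrom", "start", "end")]

  tiers <- mirna_tiers(ann, families)
  common_sites <- dplyr::filter(fragile_sites, .data$ftype == "common")
  boosted <- fragile_overlap(ann, common_sites)$in_any
  placement <- tibble::tibble(
    precursor_id = ann$precursors$precursor_id,
    tier = tiers$tier[match(ann$precursors$precursor_id, tiers$precursor_id)],
    clustered = ann$precursors$precursor_id %in%
      pre$precursor_id[pre$in_cluster],
    fragile_boosted = boosted)

  list(annotation = ann, families = families, fragile_sites = fragile_sites,
       genes = genes, qtls = qtls, placement = placement)
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

draw_alt <- function(ref, ts_tv_odds) {
  if (runif(1) < ts_tv_odds / (ts_tv_odds + 1)) {
    transition_of[[ref]]
  } else {
    sample(transversions_of[[ref]], 1)
  }
}

#' Simulate the variant table of a synthetic bundle
#'
#' Plants per-position Bernoulli SNPs inside precursors with rate
#' `background * tier multiplier * region multiplier * cluster multiplier
#' (* fragile boost inside common fragile sites)`, draws substitution
#' alleles at the configured transition:transversion odds, mixes in a
#' configurable fraction of indels and multi-allelic records, and adds
#' background-rate variants in the flanking gaps between clustered miRNAs.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param ann_parts Output of [simulate_annotation()].
#' @return List: `variants` (tibble in [read_variants()] shape) and
#'   `planted` (tibble snp_id, precursor_id for in-hairpin SNPs).
#' @export
simulate_snps <- function(config, ann_parts) {
  set.seed(child_seed(config$seed, "snps"))
  ann <- ann_parts$annotation
  pre <- ann$precursors
  placement <- ann_parts$placement
  tier_mult <- config$tier_multipliers
  reg_mult <- config$region_multipliers

  dna_comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- vector("list", nrow(pre))
  planted <- vector("list", nrow(pre))
  for (i in seq_len(nrow(pre))) {
    pid <- pre$precursor_id[i]
    L <- pre$length[i]
    info <- placement[placement$precursor_id == pid, ]
    rate0 <- config$background_rate * tier_mult[[info$tier]] *
      (if (info$clustered) config$cluster_member_multiplier else 1) *
      (if (info$fragile_boosted) config$fragile_boost else 1)
    region <- rep(1, L)
    mats <- ann$matures[ann$matures$precursor_id == pid, ]
    for (m in seq_len(nrow(mats))) {
      sp <- mats$offset[m] + 1L
      region[sp:(sp + mats$length[m] - 1L)] <- reg_mult[["mature"]]
      region[(sp + 1L):(sp + 7L)] <- reg_mult[["seed"]]
    }
    hit <- which(runif(L) < pmin(rate0 * region, 1))
    if (length(hit) == 0) next
    hp <- hit - 1L
    sense_base <- substring(pre$sequence[i], hit, hit)
    if (pre$strand[i] == "+") {
      gpos <- pre$start[i] + hp
      ref <- rna_to_dna(sense_base)
    } else {
      gpos <- pre$end[i] - 1L - hp
      ref <- unname(dna_comp[rna_to_dna(sense_base)])
    }
    alt <- unname(vapply(ref, draw_alt, character(1),
                         ts_tv_odds = config$ts_tv_odds))
    u <- runif(length(hit))
    is_indel <- u < config$indel_fraction
    is_multi <- !is_indel & u < config$indel_fraction + config$multiallelic_fraction
    for (j in which(is_indel)) {
      alt[j] <- paste0(ref[j], sample(c("A", "C", "G", "T"), 1))
    }
    for (j in which(is_multi)) {
      second <- setdiff(c("A", "C", "G", "T"), c(ref[j], alt[j]))
      alt[j] <- paste(alt[j], sample(second, 1), sep = ",")
    }
    out[[i]] <- tibble::tibble(chrom = pre$chrom[i], pos = as.integer(gpos),
                               ref = ref, alt = alt,
                               precursor_id = pid)
    planted[[i]] <- tibble::tibble(precursor_id = pid, pos = as.integer(gpos))
  }
  vars <- dplyr::bind_rows(out)

  # antisense partners share coordinates: one genomic variant, two hairpins
  if (nrow(vars) > 0) {
    vars <- dplyr::distinct(vars, .data$chrom, .data$pos, .keep_all = TRUE)
  }

  # background-rate variants in the gaps between clustered miRNAs
  clusters <- detect_clusters(ann)
  gaps <- clusters |>
    dplyr::filter(.data$clustered) |>
    dplyr::arrange(.data$cluster_id, .data$start) |>
    dplyr::group_by(.data$cluster_id, .data$chrom) |>
    dplyr::reframe(gstart = head(cummax(.data$end), -1),
                   gend = .data$start[-1]) |>
    dplyr::filter(.data$gend > .data$gstart)
  gap_rows <- purrr::map_dfr(seq_len(nrow(gaps)), function(g) {
    L <- gaps$gend[g] - gaps$gstart[g]
    hit <- which(runif(L) < config$background_rate)
    if (length(hit) == 0) return(NULL)
    ref <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    tibble::tibble(chrom = gaps$chrom[g],
                   pos = as.integer(gaps$gstart[g] + hit - 1L), ref = ref,
                   alt = unname(vapply(ref, draw_alt, character(1),
                                       ts_tv_odds = config$ts_tv_odds)),
                   precursor_id = NA_character_)
  })
  vars <- dplyr::bind_rows(vars, gap_rows)
  if (nrow(vars) == 0) {
    return(list(variants = empty_variants(),
                planted = tibble::tibble(snp_id = character(),
                                         precursor_id = character())))
  }
  vars <- dplyr::arrange(vars, .data$chrom, .data$pos)
  vars$snp_id <- sprintf("rs%06d", seq_len(nrow(vars)))
  vars$vclass <- classify_vclass(vars$ref, vars$alt)
  vars$validated <- runif(nrow(vars)) < config$validated_fraction
  first_alt <- sub(",.*$", "", vars$alt)
  vars$ancestral <- ifelse(runif(nrow(vars)) < 0.9,
                           substr(vars$ref, 1, 1), substr(first_alt, 1, 1))
  planted <- vars |>
    dplyr::filter(!is.na(.data$precursor_id)) |>
    dplyr::select("snp_id", "precursor_id")
  list(variants = tibble::as_tibble(
         vars[, c("snp_id", "chrom", "pos", "ref", "alt", "vclass",
                  "validated", "ancestral")]),
       planted = planted)
}

#' Simulate the per-population allele panel
#'
#' Null SNPs get an ancestral frequency p0 ~ Uniform(0.05, 0.95) and
#' per-population frequencies from the Balding-Nichols beta distribution
#' `Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)`; counts are binomial at 2N
#' chromosomes. Planted differentiated SNPs instead carry data only for the
#' designated population pair (the first two, lexicographically), with
#' frequencies pushed to the configured opposite extremes.
#'
#' @param config A [sim_config()].
#' @param variant_ids Candidate SNP ids (the in-hairpin SNPs).
#' @return List: `panel` (tibble snp_id, population, ref_count, alt_count)
#'   and `diff_snp_ids` / `diff_pair` truth.
#' @export
simulate_panel <- function(config, variant_ids) {
  set.seed(child_seed(config$seed, "panel"))
  pops <- sort(config$populations)
  f <- config$bn_f
  n_chrom <- 2L * config$diploid_n
  if (length(variant_ids) == 0) {
    return(list(panel = tibble::tibble(snp_id = character(),
                                       population = character(),
                                       ref_count = integer(),
                                       alt_count = integer()),
                diff_snp_ids = character(), diff_pair = pops[1:2]))
  }
  ids <- sample(variant_ids, min(config$n_panel_snps, length(variant_ids)))
  diff_ids <- sort(sample(ids, min(config$n_diff_snps, length(ids))))
  null_ids <- setdiff(ids, diff_ids)
  diff_pair <- pops[1:2]

  null_rows <- purrr::map_dfr(null_ids, function(id) {
    p0 <- runif(1, 0.05, 0.95)
    freq <- rbeta(length(pops), p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    alt <- rbinom(length(pops), n_chrom, freq)
    tibble::tibble(snp_id = id, population = pops,
                   ref_count = n_chrom - alt, alt_count = alt)
  })
  diff_rows <- purrr::map_dfr(diff_ids, function(id) {
    alt <- rbinom(2, n_chrom, config$diff_freqs)
    tibble::tibble(snp_id = id, population = diff_pair,
                   ref_count = n_chrom - alt, alt_count = alt)
  })
  panel <- dplyr::arrange(dplyr::bind_rows(null_rows, diff_rows),
                          .data$snp_id, .data$population)
  list(panel = panel, diff_snp_ids = diff_ids, diff_pair = diff_pair)
}

#' Simulate miRNA-disease associations with planted negative dependence
#'
#' Per-miRNA disease counts are Poisson with mean
#' `lambda * exp(-beta * snp_count)`; `beta = 0` gives independence. Rows
#' are expanded with synthetic disease names, so the number of rows equals
#' the sum of counts.
#'
#' @param config A [sim_config()].
#' @param snp_counts Tibble (precursor_id, snp_count).
#' @return Tibble (precursor_id, disease).
#' @export
simulate_disease <- function(config, snp_counts) {
  set.seed(child_seed(config$seed, "disease"))
  lam <- config$disease_lambda *
    exp(-config$disease_beta * snp_counts$snp_count)
  k <- rpois(nrow(snp_counts), lam)
  pool <- sprintf("disease_%03d", 1:400)
  rows <- purrr::map_dfr(which(k > 0), function(i) {
    tibble::tibble(precursor_id = snp_counts$precursor_id[i],
                   disease = sample(pool, min(k[i], length(pool))))
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(precursor_id = character(), disease = character())
  }
  rows
}

#' Generate a complete synthetic input bundle with planted truth
#'
#' Runs the annotation, variant, panel and disease generators under one
#' seed and assembles the `truth` block used by recovery tests: planted
#' per-region rates, tier and cluster multipliers, boosted fragile-site
#' membership, the disease dependence parameter and the differentiated SNP
#' ids and population pair.
#'
#' @param config A [sim_config()] (or a bare seed, promoted via
#'   `sim_config(seed = config)`).
#' @return List of class `sim_bundle` with elements annotation, families,
#'   fragile_sites, genes, qtls, variants, panel, diseases, truth, config.
#' @export
simulate_bundle <- function(config = sim_config()) {
  if (is.numeric(config)) config <- sim_config(seed = config)
  stopifnot(inherits(config, "sim_config"))
  ann_parts <- simulate_annotation(config)
  snps <- simulate_snps(config, ann_parts)
  snp_counts <- ann_parts$annotation$precursors |>
    dplyr::select("precursor_id") |>
    dplyr::left_join(dplyr::count(snps$planted, .data$precursor_id,
                                  name = "snp_count"),
                     by = "precursor_id") |>
    dplyr::mutate(snp_count = dplyr::coalesce(.data$snp_count, 0L))
  pan <- simulate_panel(config, snps$planted$snp_id)
  diseases <- simulate_disease(config, snp_counts)
  truth <- list(
    background_rate = config$background_rate,
    region_multipliers = as.list(config$region_multipliers),
    tier_multipliers = as.list(config$tier_multipliers),
    cluster_member_multiplier = config$cluster_member_multiplier,
    fragile_boost = config$fragile_boost,
    disease_beta = config$disease_beta,
    placement = ann_parts$placement,
    snp_counts = snp_counts,
    diff_snp_ids = pan$diff_snp_ids,
    diff_pair = pan$diff_pair)
  structure(list(annotation = ann_parts$annotation,
                 families = ann_parts$families,
                 fragile_sites = ann_parts$fragile_sites,
                 genes = ann_parts$genes, qtls = ann_parts$qtls,
                 variants = snps$variants, panel = pan$panel,
                 diseases = diseases, truth = truth, config = config),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic miRNA SNP bundle (seed ", x$config$seed, "): ",
      nrow(x$annotation$precursors), " precursors, ",
      nrow(x$variants), " variants, ",
      length(unique(x$panel$population)), " populations\n", sep = "")
  invisible(x)
}

#' Write a synthetic bundle to disk in its external formats
#'
#' Emits annotation.gff3 + hairpins.fa, variants.vcf, families.tsv,
#' fragile_sites.tsv (1-based inclusive coordinates), genes.bed, qtls.tsv,
#' diseases.tsv, panel.tsv and truth.json, all readable by the package's
#' loaders.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_mirna_annotation(bundle$annotation, p("annotation.gff3"),
                         p("hairpins.fa"))
  write_variants(bundle$variants, p("variants.vcf"), "vcf")
  write_families(bundle$families, p("families.tsv"))
  fr <- bundle$fragile_sites
  write_tsv_commented(tibble::tibble(name = fr$name, ftype = fr$ftype,
                                     chrom = fr$chrom, start = fr$start + 1L,
                                     end = fr$end), p("fragile_sites.tsv"))
  write_genes_bed(bundle$genes, p("genes.bed"))
  q <- bundle$qtls
  write_tsv_commented(tibble::tibble(qtl_id = q$qtl_id, trait = q$trait,
                                     chrom = q$chrom, start = q$start + 1L,
                                     end = q$end), p("qtls.tsv"))
  write_tsv_commented(bundle$diseases, p("diseases.tsv"))
  write_panel(bundle$panel, p("panel.tsv"))
  truth <- bundle$truth
  truth$placement <- NULL
  truth$snp_counts <- NULL
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a written bundle back from disk
#'
#' @param dir Directory written by [write_bundle()].
#' @return List with annotation, families, fragile_sites, genes, qtls,
#'   variants, panel, diseases (truth.json is not re-read into truth
#'   tibbles).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(annotation = read_mirna_annotation(p("annotation.gff3"), p("hairpins.fa")),
       families = read_families(p("families.tsv")),
       fragile_sites = read_fragile_sites(p("fragile_sites.tsv")),
       genes = read_genes_bed(p("genes.bed")),
       qtls = read_qtls(p("qtls.tsv")),
       variants = read_variants(p("variants.vcf"), "vcf"),
       panel = read_panel(p("panel.tsv")),
       diseases = read_diseases(p("diseases.tsv")))
}
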