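#' Run the full miRNA-SNP analysis pipeline
#'
#' Orchestrates every stage over one input bundle: variant-to-hairpin
#' mapping, per-region densities, conservation tiers, cluster detection and
#' flanking densities, fragile-site enrichment, substitution spectrum and
#' relative-MFE scoring, disease/QTL burden analyses, and the pairwise
#' population-differentiation matrix with dendrogram. Stage outputs are
#' pure functions of (inputs, configuration, seed); the popgen stage's
#' Monte-Carlo stream is seeded with a per-stage child seed so skipping
#' other stages never shifts it.
#'
#' @param bundle A `sim_bundle` or the list returned by [read_bundle()].
#' @param cluster_threshold_bp Cluster gap threshold (default 10 kb).
#' @param engine,fold_fn Folding engine for the structure stage.
#' @param mc_reps Monte-Carlo replicates per allele-frequency test.
#' @param alpha FDR threshold for the differentiation matrix.
#' @param seed Global seed for the stochastic stages.
#' @param skip Character vector of stage names to skip, among
#'   c("structure", "association", "popgen").
#' @return List of class `mirsnp_report` with one block per executed stage
#'   plus `summary` (plain named list of headline statistics).
#' @export
run_pipeline <- function(bundle, cluster_threshold_bp = 10000,
                         engine = "builtin", fold_fn = NULL,
                         mc_reps = 10000, alpha = 0.01, seed = 1,
                         skip = character()) {
  ann <- bundle$annotation
  res <- list()

  mapped <- map_snps(bundle$variants, ann)
  res$mapping <- mapped
  densities <- region_densities(mapped, ann)
  res$densities <- densities
  res$histogram <- snp_count_histogram(mapped, ann)

  with_snp <- densities |>
    dplyr::filter(.data$region == "precursor", .data$n > 0)
  pre_d <- with_snp$density
  mat_d <- densities$density[densities$region == "mature" &
                               densities$precursor_id %in% with_snp$precursor_id]
  seed_d <- densities$density[densities$region == "seed" &
                                densities$precursor_id %in% with_snp$precursor_id]
  res$density_tests <- list(
    mature_vs_precursor = mann_whitney(mat_d, pre_d, tail = "less"),
    seed_vs_mature = mann_whitney(seed_d, mat_d, tail = "less"),
    seed_vs_precursor = mann_whitney(seed_d, pre_d, tail = "less"))

  tiers <- mirna_tiers(ann, bundle$families)
  tier_d <- densities |>
    dplyr::filter(.data$region == "precursor") |>
    dplyr::inner_join(tiers, by = "precursor_id")
  d_of <- function(t) tier_d$density[tier_d$tier == t]
  res$conservation <- list(
    tiers = tiers,
    highly_vs_lowly = welch_t(d_of("highly"), d_of("lowly"), tail = "less"),
    lowly_vs_non = welch_t(d_of("lowly"), d_of("non"), tail = "less"),
    highly_vs_non = welch_t(d_of("highly"), d_of("non"), tail = "less"))

  clusters <- detect_clusters(ann, cluster_threshold_bp)
  clu_d <- densities |>
    dplyr::filter(.data$region == "precursor") |>
    dplyr::inner_join(clusters[, c("precursor_id", "clustered")],
                      by = "precursor_id")
  flank <- flanking_density(clusters, bundle$variants)
  res$clusters <- list(
    clusters = clusters, spans = cluster_spans(clusters), flanking = flank,
    clustered_vs_individual = welch_t(clu_d$density[clu_d$clustered],
                                      clu_d$density[!clu_d$clustered],
                                      tail = "less"),
    member_vs_flanking = welch_t(clu_d$density[clu_d$clustered],
                                 flank$density, tail = "less"))

  labels <- fragile_overlap(ann, bundle$fragile_sites)
  res$fragile <- list(labels = labels,
                      enrichment = fragile_enrichment(labels, mapped))

  res$genic <- genic_context(ann, bundle$genes)
  res$substitutions <- substitution_table(mapped)

  if (!"structure" %in% skip) {
    dm <- delta_mfe_table(mapped, ann, engine = engine, fold_fn = fold_fn)
    res$structure <- list(records = dm, summary = structure_summary(dm))
  }

  if (!"association" %in% skip) {
    snp_counts <- mapped |>
      dplyr::distinct(.data$snp_id, .data$precursor_id) |>
      dplyr::count(.data$precursor_id, name = "snp_count")
    per_mirna <- ann$precursors |>
      dplyr::select("precursor_id") |>
      dplyr::left_join(snp_counts, by = "precursor_id") |>
      dplyr::mutate(snp_count = dplyr::coalesce(.data$snp_count, 0L)) |>
      dplyr::left_join(disease_counts(ann, bundle$diseases),
                       by = "precursor_id") |>
      dplyr::left_join(qtl_overlap_counts(ann, bundle$qtls),
                       by = "precursor_id")
    res$association <- list(
      per_mirna = per_mirna,
      disease_test = disease_density_compare(densities, bundle$diseases),
      disease_cor = snp_disease_correlation(per_mirna),
      qtl_cor = qtl_snp_correlation(per_mirna))
  }

  if (!"popgen" %in% skip) {
    dm <- diff_matrix(bundle$panel, alpha = alpha, reps = mc_reps,
                      seed = child_seed(seed, "popgen"))
    res$popgen <- list(diff = dm,
                       dendrogram = cluster_populations(dm$matrix))
  }

  res$summary <- pipeline_summary(res, ann)
  structure(res, class = "mirsnp_report")
}

pipeline_summary <- function(res, ann) {
  n_pre <- nrow(ann$precursors)
  with_snp <- sum(res$histogram$n_precursors[res$histogram$n_snps > 0])
  s <- list(
    n_precursors = n_pre,
    n_mapped_snps = length(unique(res$mapping$snp_id)),
    n_precursors_with_snp = with_snp,
    pct_precursors_with_snp = percent_of(with_snp, n_pre),
    p_mature_vs_precursor = res$density_tests$mature_vs_precursor$p,
    p_seed_vs_mature = res$density_tests$seed_vs_mature$p,
    p_highly_vs_lowly = res$conservation$highly_vs_lowly$p,
    p_lowly_vs_non = res$conservation$lowly_vs_non$p,
    p_clustered_vs_individual = res$clusters$clustered_vs_individual$p,
    p_member_vs_flanking = res$clusters$member_vs_flanking$p,
    fragile_enrichment_p = setNames(res$fragile$enrichment$p,
                                    res$fragile$enrichment$site_class))
  if (!is.null(res$structure)) {
    s$frac_neutral <- res$structure$summary$frac_neutral
  }
  if (!is.null(res$association)) {
    s$disease_t_p <- res$association$disease_test$p
    s$disease_rho <- res$association$disease_cor$test$estimate
    s$disease_rho_p <- res$association$disease_cor$test$p
    s$qtl_rho <- res$association$qtl_cor$test$estimate
    s$qtl_rho_p <- res$association$qtl_cor$test$p
  }
  if (!is.null(res$popgen)) {
    s$diff_matrix <- res$popgen$diff$matrix
    s$newick <- res$popgen$dendrogram$newick
  }
  s
}

#' @export
print.mirsnp_report <- function(x, ...) {
  s <- x$summary
  cat("miRNA SNP pipeline report\n")
  cat("  ", s$n_mapped_snps, " SNPs mapped into ", s$n_precursors_with_snp,
      " of ", s$n_precursors, " precursors (", s$pct_precursors_with_snp,
      "%)\n", sep = "")
  cat("  density ordering (one-tailed Mann-Whitney): mature<precursor p=",
      format(s$p_mature_vs_precursor, digits = 3), ", seed<mature p=",
      format(s$p_seed_vs_mature, digits = 3), "\n", sep = "")
  if (!is.null(s$frac_neutral)) {
    cat("  substitutions with no structural influence: ",
        round(100 * s$frac_neutral), "%\n", sep = "")
  }
  invisible(x)
}

#' Write pipeline outputs (TSV tables + summary.json + report.md)
#'
#' @param report A `mirsnp_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv_commented(report$mapping, p("mapped_snps.tsv"))
  for (r in unique(report$densities$region)) {
    write_tsv_commented(
      dplyr::filter(report$densities, .data$region == r),
      p(paste0("density_", r, ".tsv")))
  }
  write_tsv_commented(report$substitutions, p("substitution_table.tsv"))
  write_tsv_commented(report$clusters$spans, p("clusters.tsv"))
  write_tsv_commented(report$fragile$enrichment, p("enrichment.tsv"))
  if (!is.null(report$structure)) {
    write_tsv_commented(report$structure$records, p("delta_mfe.tsv"))
  }
  if (!is.null(report$association)) {
    write_tsv_commented(report$association$per_mirna, p("disease_qtl.tsv"))
  }
  if (!is.null(report$popgen)) {
    write_tsv_commented(report$popgen$diff$tests, p("pair_tests.tsv"))
    m <- report$popgen$diff$matrix
    dfm <- tibble::as_tibble(m, rownames = "population")
    write_tsv_commented(dfm, p("diff_matrix.tsv"))
    writeLines(report$popgen$dendrogram$newick, p("populations.nwk"))
  }
  s <- report$summary
  s$diff_matrix <- if (!is.null(s$diff_matrix)) {
    as.data.frame(s$diff_matrix)
  }
  jsonlite::write_json(s, p("summary.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  writeLines(report_markdown(report), p("report.md"))
  invisible(dir)
}

report_markdown <- function(report) {
  s <- report$summary
  c("# miRNA SNP pipeline report", "",
    sprintf("- %d SNPs mapped into %d of %d precursors (%d%%)",
            s$n_mapped_snps, s$n_precursors_with_snp, s$n_precursors,
            s$pct_precursors_with_snp),
    sprintf("- density ordering seed < mature < precursor: p(seed<mature) = %.3g, p(mature<precursor) = %.3g",
            s$p_seed_vs_mature, s$p_mature_vs_precursor),
    sprintf("- conservation: p(highly<lowly) = %.3g, p(lowly<non) = %.3g",
            s$p_highly_vs_lowly, s$p_lowly_vs_non),
    sprintf("- clusters: p(clustered<individual) = %.3g, p(member<flanking) = %.3g",
            s$p_clustered_vs_individual, s$p_member_vs_flanking),
    if (!is.null(s$frac_neutral))
      sprintf("- substitutions with no structural influence: %d%%",
              round(100 * s$frac_neutral)),
    if (!is.null(s$disease_rho))
      sprintf("- SNP count vs disease count: rho = %.3f (p = %.3g)",
              s$disease_rho, s$disease_rho_p))
}
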