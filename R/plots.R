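#' Density distributions across hairpin regions
#'
#' Boxplots of per-unit SNP density for precursor, mature and seed regions
#' (units with at least one SNP in their precursor by default, matching the
#' headline comparison).
#'
#' @param densities Tibble from [region_densities()].
#' @param nonzero_precursors_only Restrict to precursors carrying a SNP.
#' @return A ggplot object.
#' @export
plot_density_distribution <- function(densities, nonzero_precursors_only = TRUE) {
  if (nonzero_precursors_only) {
    keep <- densities$precursor_id[densities$region == "precursor" &
                                     densities$n > 0]
    densities <- dplyr::filter(densities, .data$precursor_id %in% keep)
  }
  densities$region <- factor(densities$region,
                             levels = c("precursor", "mature", "seed"))
  ggplot2::ggplot(densities,
                  ggplot2::aes(x = .data$region, y = .data$density)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::labs(x = NULL, y = "SNP density (SNPs / bp)") +
    ggplot2::theme_minimal()
}

#' Histogram of SNP counts per precursor
#' @param histogram Tibble from [snp_count_histogram()].
#' @return A ggplot object.
#' @export
plot_snp_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$n_snps, y = .data$n_precursors)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "SNPs per precursor", y = "precursors") +
    ggplot2::theme_minimal()
}

#' Distribution of relative MFE changes
#' @param records Tibble from [delta_mfe_table()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_delta_mfe <- function(records, bins = 60) {
  df <- dplyr::filter(records, !is.na(.data$rel_change))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_change)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "relative MFE change ((mut - anc) / |anc|)",
                  y = "substitutions") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_delta_mfe autoplot method for the per-substitution
#'   records joined with their class labels.
#' @param object,... autoplot arguments.
#' @export
autoplot.pairwise_diff <- function(object, ...) {
  m <- object$matrix
  df <- tibble::as_tibble(m, rownames = "pop_a") |>
    tidyr::pivot_longer(-"pop_a", names_to = "pop_b", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pop_a, y = .data$pop_b,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("SNPs q<", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Burden-correlation curve (grouped means)
#'
#' @param object A `mirsnp_burden_cor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirsnp_burden_cor <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$group, y = .data$mean_value)) +
    ggplot2::geom_line(colour = "goldenrod") +
    ggplot2::geom_point(colour = "darkgreen", shape = 17, size = 2) +
    ggplot2::labs(x = object$x, y = paste("mean", object$y)) +
    ggplot2::theme_minimal()
}
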