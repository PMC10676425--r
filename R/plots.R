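#' Volcano-style plot of k-mer enrichment
#'
#' Log2 enrichment against -log10 Bonferroni-adjusted p, one dot per
#' k-mer, with the top hits labelled in the RNA alphabet.
#'
#' @param object A `kmer_enrichment` tibble.
#' @param label_top Number of top k-mers to label (default 5).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kmer_enrichment <- function(object, label_top = 5L, ...) {
  df <- tibble::as_tibble(object)
  df$neglog_p <- -log10(pmax(df$p_adj, 1e-300))
  top <- utils::head(df[order(df$p_adj, -df$enrichment), ], label_top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_enrichment,
                                   y = .data$neglog_p)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = top, color = "firebrick") +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(label = as_rna_kmer(.data$kmer)),
                       vjust = -0.6, size = 3) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "log2 enrichment (fg / bg)",
                  y = "-log10 adjusted p (Bonferroni)") +
    ggplot2::theme_classic()
}

#' Plot an RNA splicing map profile
#'
#' Per-exon peak density along the meta-exon axis (exon body collapsed to
#' the 0 bin), observed profile against the bootstrap null rate, with
#' FDR stars where the Poisson tail is significant.
#'
#' @param object A `meta_exon_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meta_exon_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  n_ex <- attr(object, "n_exons")
  df$x <- (df$bin_start + df$bin_end) / 2
  df$null_per_exon <- df$lambda / n_ex
  sig <- df[df$fdr <= 0.05 & df$side != "exon", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$per_exon), color = "#2166ac") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_per_exon),
                       linetype = "dashed", color = "grey40") +
    ggplot2::geom_point(data = sig, ggplot2::aes(y = .data$per_exon),
                        shape = 8, color = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::labs(x = "position relative to exon (nt)",
                  y = "peaks per exon",
                  title = attr(object, "label")) +
    ggplot2::theme_classic()
}

#' Heatmap of shared-event ΔPSI across datasets
#'
#' @param concordance Output of [dpsi_concordance_matrix()].
#' @return A ggplot object; grey tiles mark events not significant in that
#'   dataset.
#' @export
plot_dpsi_concordance <- function(concordance) {
  long <- tidyr::pivot_longer(
    concordance, cols = -c("key", "gene_symbol", "event_type"),
    names_to = "dataset", values_to = "dpsi"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$key,
                                     fill = .data$dpsi)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey80",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ΔPSI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Bar plot of the peak genomic-feature distribution
#'
#' @param distribution Output of [peak_feature_distribution()].
#' @return A ggplot object (genic fractions only).
#' @export
plot_peak_features <- function(distribution) {
  df <- distribution[distribution$feature != "intergenic", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature,
                                   y = 100 * .data$frac_genic)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "% of genic peaks") +
    ggplot2::theme_classic()
}
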