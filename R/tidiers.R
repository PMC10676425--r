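#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a k-mer enrichment result
#'
#' @param x A `kmer_enrichment` tibble.
#' @param ... Ignored.
#' @return A plain tibble, one row per k-mer, sorted by adjusted p.
#' @exportS3Method generics::tidy
tidy.kmer_enrichment <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a k-mer enrichment result
#'
#' @param x A `kmer_enrichment` tibble.
#' @param ... Ignored.
#' @return Tibble with `k`, `n_kmers`, `fg_total`, `n_significant`
#'   (adjusted p < 0.05), `top_kmer`, `top_p_adj`.
#' @exportS3Method generics::glance
glance.kmer_enrichment <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"), n_kmers = nrow(x), fg_total = x$fg_total[1],
    n_significant = sum(x$p_adj < 0.05),
    top_kmer = x$kmer[1], top_p_adj = x$p_adj[1]
  )
}

#' Tidy a meta-exon profile
#'
#' @param x A `meta_exon_profile`.
#' @param ... Ignored.
#' @return A plain tibble of per-bin rows.
#' @exportS3Method generics::tidy
tidy.meta_exon_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a meta-exon profile
#'
#' @param x A `meta_exon_profile`.
#' @param ... Ignored.
#' @return Tibble with `n_exons`, `n_insensitive`, `total_observed`,
#'   `n_bins`, `n_significant` (FDR <= 0.05), `min_fdr`.
#' @exportS3Method generics::glance
glance.meta_exon_profile <- function(x, ...) {
  tibble::tibble(
    n_exons = attr(x, "n_exons"),
    n_insensitive = attr(x, "n_insensitive"),
    total_observed = sum(x$observed), n_bins = nrow(x),
    n_significant = sum(x$fdr <= 0.05), min_fdr = min(x$fdr)
  )
}

#' Tidy the four flank enrichment tests
#'
#' @param x A `flank_test` tibble.
#' @param ... Ignored.
#' @return A plain tibble.
#' @exportS3Method generics::tidy
tidy.flank_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}
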