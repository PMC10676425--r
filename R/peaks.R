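#' Stringent CLIP-peak filter
#'
#' Retains peaks with `fold_enrichment >= min_fe` (inclusive) and
#' `pvalue < max_p` (strict), the conventional top-target cut for
#' input-normalized CLIP peaks. Idempotent: filtering the result again
#' changes nothing.
#'
#' @param peaks Peak tibble with `fold_enrichment` and `pvalue`.
#' @param min_fe Fold-enrichment floor, inclusive (default 2).
#' @param max_p p-value ceiling, strict (default 1e-3).
#' @return The retained peaks, original order preserved.
#' @export
filter_peaks_stringent <- function(peaks, min_fe = 2, max_p = 1e-3) {
  pk <- tibble::as_tibble(peaks)
  pk[pk$fold_enrichment >= min_fe & pk$pvalue < max_p, , drop = FALSE]
}

#' Peak width statistics
#'
#' @param peaks Non-empty peak tibble.
#' @return Tibble with one row: `n_peaks`, `mean_width`, `median_width`,
#'   `sd_width` (nt).
#' @export
peak_width_stats <- function(peaks) {
  pk <- tibble::as_tibble(peaks)
  if (nrow(pk) == 0L) stop("empty peak set", call. = FALSE)
  w <- pk$end - pk$start
  tibble::tibble(n_peaks = length(w), mean_width = mean(w),
                 median_width = stats::median(w),
                 sd_width = if (length(w) > 1L) stats::sd(w) else 0)
}

#' Genomic-feature distribution of a peak set
#'
#' Labels every peak via [annotate_interval_feature()] and reports the
#' fraction of genic peaks (all labels except intergenic) in each feature
#' class. The genic fractions sum to 1.
#'
#' @param peaks Peak tibble.
#' @param annotation A `genome_annotation`.
#' @return Tibble: `feature`, `n`, `frac_genic` (NA for intergenic),
#'   `percent_genic` (rounded to 0.1).
#' @export
peak_feature_distribution <- function(peaks, annotation) {
  lab <- annotate_interval_feature(peaks, annotation)
  counts <- dplyr::count(lab, .data$feature, .drop = FALSE, name = "n")
  genic_total <- sum(counts$n[counts$feature != "intergenic"])
  counts$frac_genic <- ifelse(
    counts$feature == "intergenic", NA_real_,
    if (genic_total > 0L) counts$n / genic_total else NA_real_
  )
  counts$percent_genic <- round(100 * counts$frac_genic, 1)
  counts
}

#' Summarize a peak set
#'
#' Convenience wrapper combining peak count, bound-gene count, width
#' statistics, and the genomic-feature distribution.
#'
#' @param peaks Peak tibble.
#' @param annotation A `genome_annotation`.
#' @return A `peak_set_summary` list: `n_peaks`, `n_genes`, `widths`
#'   (from [peak_width_stats()]), `features`
#'   (from [peak_feature_distribution()]).
#' @export
summarize_peak_set <- function(peaks, annotation) {
  pg <- assign_peaks_to_genes(peaks, annotation)
  structure(
    list(n_peaks = nrow(peaks),
         n_genes = length(pg$bound_genes),
         widths = peak_width_stats(peaks),
         features = peak_feature_distribution(peaks, annotation)),
    class = "peak_set_summary"
  )
}

#' @export
print.peak_set_summary <- function(x, ...) {
  cat("<peak_set_summary> ", x$n_peaks, " peaks in ", x$n_genes,
      " genes; mean width ", round(x$widths$mean_width, 1), " nt\n",
      sep = "")
  f <- x$features[x$features$feature != "intergenic", ]
  cat("  ", paste(sprintf("%s %.1f%%", f$feature, 100 * f$frac_genic),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}
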