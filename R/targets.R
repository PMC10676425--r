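#' Call direct RBP splicing targets
#'
#' A direct target is a gene that is both bound (has at least one CLIP
#' peak) and significantly alternatively spliced. All significant events in
#' the intersected genes are counted, broken down by event type.
#'
#' @param bound_genes Character vector of bound gene identifiers (e.g.
#'   `assign_peaks_to_genes(...)$bound_genes`).
#' @param significant_events Significant event tibble (from
#'   [filter_significant()]); gene identifiers are harmonized
#'   case-insensitively by symbol.
#' @param by Column of the events used for matching, `"gene_symbol"`
#'   (default) or `"gene_id"`.
#' @return A `direct_target_report` list: `bound_genes`, `spliced_genes`,
#'   `direct_targets` (all harmonized), `n_events` (events in direct-target
#'   genes), `events_by_type` (tibble), `events` (the covered event rows).
#' @export
call_direct_targets <- function(bound_genes, significant_events,
                                by = c("gene_symbol", "gene_id")) {
  by <- match.arg(by)
  ev <- tibble::as_tibble(significant_events)
  bound <- sort(unique(harmonize_gene(bound_genes)))
  spliced <- sort(unique(harmonize_gene(ev[[by]])))
  direct <- intersect(bound, spliced)
  covered <- ev[harmonize_gene(ev[[by]]) %in% direct, , drop = FALSE]
  by_type <- dplyr::count(covered, .data$event_type, name = "n")
  structure(
    list(bound_genes = bound, spliced_genes = spliced,
         direct_targets = direct, n_events = nrow(covered),
         events_by_type = by_type, events = covered),
    class = "direct_target_report"
  )
}

#' @export
print.direct_target_report <- function(x, ...) {
  cat("<direct_target_report> ", length(x$direct_targets),
      " direct-target genes (", length(x$bound_genes), " bound, ",
      length(x$spliced_genes), " spliced); ", x$n_events,
      " covered events\n", sep = "")
  if (nrow(x$events_by_type) > 0L) {
    cat("  ", paste(sprintf("%s %d", x$events_by_type$event_type,
                            x$events_by_type$n), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Count peaks in the flanking introns of each event
#'
#' For every event, counts peak midpoints in the upstream intron (between
#' the upstream-exon end and the regulated-exon start, in transcript
#' orientation), the downstream intron, and within the regulated exon
#' itself. Up/downstream swap genomic sides on the minus strand. Events
#' whose flanking exons overlap the regulated exon are skipped with a
#' warning. A peak may count for several events (overlapping geometries are
#' real) but at most once per compartment per event.
#'
#' @param events Event tibble with regulated-exon and flanking-exon
#'   coordinates.
#' @param peaks Peak tibble (strand-matched by midpoint).
#' @param which_exon For MXE events, which alternative exon (1 or 2) the
#'   compartments are relative to; default 1. Ignored for other types.
#' @return Tibble: one row per retained event with `event_id`,
#'   `gene_symbol`, `event_type`, `upstream_peaks`, `downstream_peaks`,
#'   `exon_peaks`.
#' @export
peaks_by_flanking_intron <- function(events, peaks, which_exon = 1L) {
  ev <- tibble::as_tibble(events)
  pk <- tibble::as_tibble(peaks)
  use2 <- which_exon == 2L & ev$event_type == "MXE"
  ex_s <- ifelse(use2, ev$exon2_start, ev$exon1_start)
  ex_e <- ifelse(use2, ev$exon2_end, ev$exon1_end)
  # nearest genomic neighbours among the flanking exons and, for MXE, the
  # other alternative exon (the introns of interest end at it)
  other_s <- ifelse(ev$event_type == "MXE",
                    ifelse(use2, ev$exon1_start, ev$exon2_start),
                    NA_integer_)
  other_e <- ifelse(ev$event_type == "MXE",
                    ifelse(use2, ev$exon1_end, ev$exon2_end),
                    NA_integer_)
  nb_end <- function(i) {
    ends <- c(ev$upstream_end[i], ev$downstream_end[i], other_e[i])
    ends <- ends[!is.na(ends) & ends <= ex_s[i]]
    if (length(ends) == 0L) NA_integer_ else max(ends)
  }
  nb_start <- function(i) {
    sts <- c(ev$upstream_start[i], ev$downstream_start[i], other_s[i])
    sts <- sts[!is.na(sts) & sts >= ex_e[i]]
    if (length(sts) == 0L) NA_integer_ else min(sts)
  }
  lft_e <- vapply(seq_len(nrow(ev)), nb_end, integer(1))
  rgt_s <- vapply(seq_len(nrow(ev)), nb_start, integer(1))
  ok <- !is.na(ex_s) & !is.na(lft_e) & !is.na(rgt_s) &
    lft_e <= ex_s & rgt_s >= ex_e
  if (any(!ok)) {
    warning(sum(!ok), " event(s) with malformed geometry skipped",
            call. = FALSE)
    ev <- ev[ok, , drop = FALSE]
    ex_s <- ex_s[ok]; ex_e <- ex_e[ok]
    lft_e <- lft_e[ok]; rgt_s <- rgt_s[ok]
  }
  mid <- peak_midpoint(pk)
  count_in <- function(int_s, int_e) {
    vapply(seq_len(nrow(ev)), function(i) {
      sum(pk$contig == ev$contig[i] & pk$strand == ev$strand[i] &
            mid >= int_s[i] & mid < int_e[i])
    }, integer(1))
  }
  left_n <- count_in(lft_e, ex_s)     # intron genomically left of the exon
  right_n <- count_in(ex_e, rgt_s)
  exon_n <- count_in(ex_s, ex_e)
  minus <- ev$strand == "-"
  tibble::tibble(
    event_id = ev$event_id, gene_symbol = ev$gene_symbol,
    event_type = ev$event_type,
    upstream_peaks = ifelse(minus, right_n, left_n),
    downstream_peaks = ifelse(minus, left_n, right_n),
    exon_peaks = exon_n
  )
}
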