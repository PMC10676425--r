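cond_read_support <- function(events, min_reads) {
  r1 <- vapply(seq_len(nrow(events)), function(i) {
    sum(events$ijc_1[[i]], events$sjc_1[[i]], na.rm = TRUE)
  }, numeric(1))
  r2 <- vapply(seq_len(nrow(events)), function(i) {
    sum(events$ijc_2[[i]], events$sjc_2[[i]], na.rm = TRUE)
  }, numeric(1))
  r1 >= min_reads | r2 >= min_reads
}

#' Filter events to the significantly alternatively spliced set
#'
#' Retains events with `fdr < fdr_max`, `|dpsi| >= dpsi_min`, and total
#' junction-read support (inclusion + skipping, summed over replicates) of
#' at least `min_reads` in at least one of the two conditions. The retained
#' events gain `significant = TRUE`, a regulation `direction`
#' (`"included"` when `dpsi > 0` under the convention
#' dpsi = mean PSI(condition 1 = control) − mean PSI(condition 2 = depleted),
#' i.e. the RBP promotes inclusion of that exon; `"skipped"` otherwise) and
#' a `dataset_id`.
#'
#' @param events Event tibble from [read_rmats_table()].
#' @param fdr_max FDR cutoff, strict (`< 0.05` by default).
#' @param dpsi_min Minimum `|dpsi|`; 0.01 and 0.05 are the conventional
#'   choices.
#' @param min_reads Read-support floor per condition (default 20).
#' @param dataset_id Optional label recorded on every retained event.
#' @return The retained events, with `significant`, `direction`,
#'   `dataset_id` columns. Events with missing FDR are excluded (a warning
#'   reports how many).
#' @export
filter_significant <- function(events, fdr_max = 0.05, dpsi_min = 0.01,
                               min_reads = 20, dataset_id = NA_character_) {
  ev <- tibble::as_tibble(events)
  if (nrow(ev) == 0L) return(annotate_sig(ev, dataset_id))
  na_fdr <- is.na(ev$fdr)
  if (any(na_fdr)) {
    warning(sum(na_fdr), " event(s) with missing FDR excluded",
            call. = FALSE)
    ev <- ev[!na_fdr, , drop = FALSE]
  }
  keep <- ev$fdr < fdr_max & !is.na(ev$dpsi) & abs(ev$dpsi) >= dpsi_min &
    cond_read_support(ev, min_reads)
  annotate_sig(ev[keep, , drop = FALSE], dataset_id)
}

annotate_sig <- function(ev, dataset_id) {
  ev$significant <- rep(TRUE, nrow(ev))
  ev$direction <- ifelse(ev$dpsi > 0, "included", "skipped")
  ev$dataset_id <- rep(dataset_id, length.out = nrow(ev))
  ev
}

#' Select splicing-insensitive events
#'
#' Insensitive events have `fdr > fdr_min` (strict, so events at exactly
#' the cutoff fall in neither set) and pass the same read-support rule as
#' the significant set. They supply the background exons for k-mer and
#' RNA-map null construction.
#'
#' @inheritParams filter_significant
#' @param fdr_min FDR lower bound, strict (`> 0.05` by default).
#' @param apply_read_floor Set `FALSE` to skip the read-support rule.
#' @return The insensitive events. Errors if the result is empty, since a
#'   null cannot be built from nothing.
#' @export
select_insensitive <- function(events, fdr_min = 0.05, min_reads = 20,
                               apply_read_floor = TRUE) {
  ev <- tibble::as_tibble(events)
  keep <- !is.na(ev$fdr) & ev$fdr > fdr_min
  if (apply_read_floor) keep <- keep & cond_read_support(ev, min_reads)
  out <- ev[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no insensitive events: null construction impossible",
         call. = FALSE)
  }
  out$significant <- FALSE
  out
}

harmonize_gene <- function(x) toupper(trimws(x))

#' Write an event set as a flat TSV
#'
#' Mirrors the rMATS columns (replicate vectors comma-joined) plus the
#' `significant`, `direction`, and `dataset_id` annotations when present.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  ev <- tibble::as_tibble(events)
  for (col in c("ijc_1", "sjc_1", "ijc_2", "sjc_2")) {
    if (is.list(ev[[col]])) ev[[col]] <- fmt_num_list(ev[[col]], 0)
  }
  for (col in c("inc_level_1", "inc_level_2")) {
    if (is.list(ev[[col]])) ev[[col]] <- fmt_num_list(ev[[col]])
  }
  readr::write_tsv(ev, path, progress = FALSE)
  invisible(path)
}

#' Intersect significant gene sets across datasets
#'
#' Gene identifiers are harmonized by symbol, case-insensitively, so sets
#' from different datasets (or species orthologs sharing symbols) can be
#' compared. All exclusive Venn regions are counted.
#'
#' @param sets Named list (length >= 2, unique names) of either event
#'   tibbles carrying `gene_symbol` or plain character vectors of gene
#'   symbols.
#' @return An `event_set_comparison`: list with `gene_sets` (harmonized),
#'   `regions` (tibble `region`, `n` — exclusive Venn region counts, region
#'   labelled by the `+`-joined member sets), `common` (genes in every set)
#'   and `pairwise` (tibble of pairwise intersection sizes).
#' @export
intersect_gene_level <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == "")) {
    stop("sets must have unique, non-empty names", call. = FALSE)
  }
  gs <- lapply(sets, function(s) {
    v <- if (is.data.frame(s)) s$gene_symbol else s
    sort(unique(harmonize_gene(v)))
  })
  k <- length(gs)
  all_genes <- sort(unique(unlist(gs)))
  member <- vapply(gs, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  regions <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    inc <- as.logical(combos[i, ])
    in_region <- rowSums(member[, inc, drop = FALSE]) == sum(inc) &
      rowSums(member[, !inc, drop = FALSE]) == 0L
    tibble::tibble(region = paste(names(gs)[inc], collapse = "+"),
                   n = sum(in_region))
  })
  pairs <- utils::combn(names(gs), 2L)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    tibble::tibble(set_a = a, set_b = b,
                   n = length(intersect(gs[[a]], gs[[b]])))
  })
  structure(list(gene_sets = gs, regions = regions,
                 common = Reduce(intersect, gs), pairwise = pairwise),
            class = "event_set_comparison")
}

#' @export
print.event_set_comparison <- function(x, ...) {
  cat("<event_set_comparison> ", length(x$gene_sets), " sets (",
      paste(names(x$gene_sets), collapse = ", "), ")\n", sep = "")
  cat("  sizes: ", paste(vapply(x$gene_sets, length, integer(1)),
                         collapse = ", "), "\n", sep = "")
  cat("  common to all: ", length(x$common), " genes\n", sep = "")
  invisible(x)
}

event_match_key <- function(ev) {
  paste(ev$event_type, ev$contig, ev$strand, ev$exon1_start, ev$exon1_end,
        ifelse(is.na(ev$exon2_start), ".", ev$exon2_start),
        ifelse(is.na(ev$exon2_end), ".", ev$exon2_end), sep = ":")
}

#' Match events across two datasets at the exon level
#'
#' Events match when they share the event type, contig, strand, and the
#' exact regulated-exon interval(s) — both alternative exons for MXE. A
#' coordinate shifted by a single nucleotide does not match. Each event is
#' used at most once.
#'
#' @param set_a,set_b Event tibbles (same genome build).
#' @return Tibble of matched pairs with both `dpsi` values and a
#'   `concordant` flag (equal ΔPSI sign).
#' @export
intersect_event_level <- function(set_a, set_b) {
  a <- tibble::as_tibble(set_a); b <- tibble::as_tibble(set_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble::tibble(key = character(), gene_symbol = character(),
                          event_type = character(), dpsi_a = numeric(),
                          dpsi_b = numeric(), concordant = logical()))
  }
  a$key <- event_match_key(a); b$key <- event_match_key(b)
  a <- a[!duplicated(a$key), , drop = FALSE]
  b <- b[!duplicated(b$key), , drop = FALSE]
  m <- dplyr::inner_join(
    dplyr::select(a, "key", "gene_symbol", "event_type", dpsi_a = "dpsi"),
    dplyr::select(b, "key", dpsi_b = "dpsi"),
    by = "key"
  )
  m$concordant <- sign(m$dpsi_a) == sign(m$dpsi_b)
  m
}

#' ΔPSI concordance matrix of shared events across datasets
#'
#' Builds the wide table behind a shared-exon heatmap: one row per event
#' observed as significant in at least `min_datasets` datasets, one ΔPSI
#' column per dataset, `NA` where the event was not significant in that
#' dataset.
#'
#' @param sets Named list (>= 2) of significant event tibbles.
#' @param min_datasets Minimum number of datasets an event must appear in
#'   (default 2).
#' @return Tibble: `key`, `gene_symbol`, `event_type`, then one `dpsi`
#'   column per dataset name.
#' @export
dpsi_concordance_matrix <- function(sets, min_datasets = 2L) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  long <- purrr::map_dfr(names(sets), function(nm) {
    ev <- tibble::as_tibble(sets[[nm]])
    if (nrow(ev) == 0L) return(NULL)
    tibble::tibble(key = event_match_key(ev),
                   gene_symbol = harmonize_gene(ev$gene_symbol),
                   event_type = ev$event_type,
                   dataset = nm, dpsi = ev$dpsi)
  })
  long <- dplyr::distinct(long, .data$key, .data$dataset, .keep_all = TRUE)
  keep <- dplyr::count(long, .data$key)
  keep <- keep$key[keep$n >= min_datasets]
  long <- dplyr::filter(long, .data$key %in% keep)
  tidyr::pivot_wider(long, id_cols = c("key", "gene_symbol", "event_type"),
                     names_from = "dataset", values_from = "dpsi")
}

#' Candidate RBP screen on a differential-expression table
#'
#' Filters a gene-level expression results table (produced upstream by any
#' differential-expression engine) to RBP-list genes that are both highly
#' expressed — group mean above `min_mean` in at least one group — and
#' significantly changed (`padj < padj_max`), then emits a per-row
#' mean-centered expression matrix for plotting.
#'
#' @param expression_table Tibble with columns `gene`, `padj`, and the
#'   group-mean columns named in `mean_cols`.
#' @param rbp_genes Character vector of RBP gene symbols (e.g. an RNA
#'   splicing GO term member list). Must be non-empty.
#' @param min_mean Expression floor on the group means (default 1500,
#'   baseMean scale).
#' @param padj_max Adjusted-p cutoff (default 0.05, strict).
#' @param mean_cols Names of the two (or more) group-mean columns.
#' @return An `rbp_screen` list: `candidates` (filtered tibble with a
#'   `direction` column, `"up"` when the last group mean exceeds the first),
#'   and `centered` (matrix of candidate group means, rows centered to 0).
#' @export
candidate_rbp_screen <- function(expression_table, rbp_genes,
                                 min_mean = 1500, padj_max = 0.05,
                                 mean_cols = c("mean_1", "mean_2")) {
  if (length(rbp_genes) == 0L) stop("RBP gene list is empty", call. = FALSE)
  tb <- tibble::as_tibble(expression_table)
  stopifnot(all(c("gene", "padj", mean_cols) %in% names(tb)))
  tb <- dplyr::filter(tb, harmonize_gene(.data$gene) %in%
                        harmonize_gene(rbp_genes))
  mm <- as.matrix(tb[, mean_cols])
  keep <- apply(mm, 1L, max) > min_mean & !is.na(tb$padj) &
    tb$padj < padj_max
  cand <- tb[keep, , drop = FALSE]
  mm <- mm[keep, , drop = FALSE]
  cand$direction <- ifelse(mm[, length(mean_cols)] > mm[, 1L], "up", "down")
  centered <- mm - rowMeans(mm)
  rownames(centered) <- cand$gene
  structure(list(candidates = cand, centered = centered),
            class = "rbp_screen")
}

#' @export
print.rbp_screen <- function(x, ...) {
  cat("<rbp_screen> ", nrow(x$candidates), " candidate RBP(s): ",
      sum(x$candidates$direction == "up"), " up, ",
      sum(x$candidates$direction == "down"), " down\n", sep = "")
  invisible(x)
}
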