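peak_midpoint <- function(peaks) {
  as.integer(floor((peaks$start + peaks$end) / 2))
}

# which peak midpoints fall inside any interval of `feat`, strand-matched
mid_in_feature <- function(mid, contig, strand, feat) {
  if (nrow(feat) == 0L) return(rep(FALSE, length(mid)))
  q <- GenomicRanges::GRanges(contig,
                              IRanges::IRanges(mid + 1L, width = 1L),
                              strand = strand)
  s <- GenomicRanges::GRanges(feat$contig,
                              IRanges::IRanges(feat$start + 1L, feat$end),
                              strand = feat$strand)
  IRanges::overlapsAny(q, s, ignore.strand = FALSE)
}

#' Assign a genomic-feature label to each peak
#'
#' Each peak is labelled by its midpoint, matched on strand (CLIP peaks are
#' stranded), with the fixed precedence
#' `CDS-exon > 3UTR > 5UTR > intron > intergenic` across all overlapping
#' transcripts. When the annotation carries no CDS features, exonic
#' midpoints are labelled `CDS-exon`.
#'
#' @param peaks Peak tibble (columns `contig`, `start`, `end`, `strand`).
#' @param annotation A `genome_annotation`.
#' @return The peak tibble with an added `feature` factor over
#'   `c("CDS-exon", "3UTR", "5UTR", "intron", "intergenic")`.
#' @export
annotate_interval_feature <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  pk <- tibble::as_tibble(peaks)
  mid <- peak_midpoint(pk)
  exonic <- if (nrow(annotation$cds) > 0L) annotation$cds else
    annotation$exons
  layers <- list(
    `CDS-exon` = exonic,
    `3UTR` = annotation$utr3,
    `5UTR` = annotation$utr5,
    intron = annotation$introns
  )
  lab <- rep("intergenic", nrow(pk))
  unset <- rep(TRUE, nrow(pk))
  for (nm in names(layers)) {
    hit <- mid_in_feature(mid, pk$contig, pk$strand, layers[[nm]])
    lab[unset & hit] <- nm
    unset <- unset & !hit
  }
  pk$feature <- factor(lab, levels = c("CDS-exon", "3UTR", "5UTR",
                                       "intron", "intergenic"))
  pk
}

#' Assign peaks to genes by midpoint
#'
#' A peak is assigned to every gene whose span contains the peak midpoint on
#' the same strand; peaks in the overlap of two same-strand genes are
#' assigned to both. Intergenic peaks are dropped from the assignment table.
#'
#' @param peaks Peak tibble.
#' @param annotation A `genome_annotation`.
#' @return A list with `assignments` (tibble `peak_id`, `gene_id`, one row
#'   per peak-gene pair) and `bound_genes` (character vector of genes with
#'   at least one assigned peak).
#' @export
assign_peaks_to_genes <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  pk <- tibble::as_tibble(peaks)
  g <- annotation$genes
  if (nrow(pk) == 0L || nrow(g) == 0L) {
    return(list(assignments = tibble::tibble(peak_id = character(),
                                             gene_id = character()),
                bound_genes = character(0)))
  }
  mid <- peak_midpoint(pk)
  q <- GenomicRanges::GRanges(pk$contig,
                              IRanges::IRanges(mid + 1L, width = 1L),
                              strand = pk$strand)
  s <- GenomicRanges::GRanges(g$contig,
                              IRanges::IRanges(g$start + 1L, g$end),
                              strand = g$strand)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
  assignments <- tibble::tibble(
    peak_id = pk$peak_id[S4Vectors::queryHits(hits)],
    gene_id = g$gene_id[S4Vectors::subjectHits(hits)]
  )
  assignments <- dplyr::arrange(assignments, .data$peak_id, .data$gene_id)
  list(assignments = assignments,
       bound_genes = sort(unique(assignments$gene_id)))
}
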