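#' Read a GTF gene annotation
#'
#' Parses Ensembl-style GTF (1-based closed coordinates, attributes
#' `gene_id` and `transcript_id`) into an internal strand-aware gene model.
#' All internal coordinates are 0-based half-open; the conversion happens
#' once, at this boundary. Introns are derived as the gaps between
#' consecutive exons of a transcript; when CDS features are present, 5' and
#' 3' UTR intervals are derived from the exonic sequence outside the CDS
#' span.
#'
#' @param path Path to a GTF file with gene/transcript/exon (optionally CDS)
#'   features.
#' @return A `genome_annotation` object: a list of tibbles `genes`,
#'   `transcripts`, `exons`, `introns`, `cds`, `utr5`, `utr3`, each with
#'   columns `contig`, `start`, `end` (0-based half-open), `strand` and the
#'   relevant identifiers.
#' @export
read_gtf <- function(path) {
  stopifnot(file.exists(path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  df <- tibble::as_tibble(as.data.frame(gr))
  if (nrow(df) == 0L) stop("GTF contains no features", call. = FALSE)
  df <- dplyr::transmute(
    df,
    contig = as.character(.data$seqnames),
    start = as.integer(.data$start) - 1L,   # to 0-based half-open
    end = as.integer(.data$end),
    strand = as.character(.data$strand),
    type = as.character(.data$type),
    gene_id = as.character(.data$gene_id),
    transcript_id = if ("transcript_id" %in% names(df))
      as.character(.data$transcript_id) else NA_character_
  )
  if (any(df$start >= df$end)) {
    stop("GTF feature with start > end", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("every GTF feature must have strand '+' or '-'", call. = FALSE)
  }
  ex <- dplyr::filter(df, .data$type == "exon")
  if (nrow(ex) == 0L) stop("GTF contains no exon features", call. = FALSE)
  if (anyNA(ex$transcript_id)) {
    stop("exon feature without a transcript_id parent", call. = FALSE)
  }
  ex <- dplyr::arrange(ex, .data$contig, .data$transcript_id, .data$start)
  ex <- dplyr::group_by(ex, .data$transcript_id)
  ex <- dplyr::mutate(ex, exon_rank = dplyr::row_number())
  ex <- dplyr::ungroup(ex)

  transcripts <- dplyr::summarise(
    dplyr::group_by(ex, .data$gene_id, .data$transcript_id,
                    .data$contig, .data$strand),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
  genes <- dplyr::summarise(
    dplyr::group_by(transcripts, .data$gene_id, .data$contig, .data$strand),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )

  introns <- derive_introns(ex)
  cds <- dplyr::filter(df, .data$type == "CDS")
  cds <- dplyr::select(cds, "contig", "start", "end", "strand",
                       "gene_id", "transcript_id")
  utr <- derive_utrs(ex, cds)

  structure(
    list(
      genes = dplyr::select(genes, "gene_id", "contig", "start", "end",
                            "strand"),
      transcripts = dplyr::select(transcripts, "gene_id", "transcript_id",
                                  "contig", "start", "end", "strand"),
      exons = dplyr::select(ex, "gene_id", "transcript_id", "contig",
                            "start", "end", "strand", "exon_rank"),
      introns = introns,
      cds = tibble::as_tibble(cds),
      utr5 = utr$utr5,
      utr3 = utr$utr3
    ),
    class = "genome_annotation"
  )
}

# gaps between consecutive exons, per transcript (strand-free derivation)
derive_introns <- function(exons) {
  ex <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  out <- dplyr::reframe(
    dplyr::group_by(ex, .data$gene_id, .data$transcript_id,
                    .data$contig, .data$strand),
    istart = utils::head(.data$end, -1L),
    iend = utils::tail(.data$start, -1L)
  )
  out <- dplyr::rename(out, start = "istart", end = "iend")
  out <- dplyr::filter(out, !is.na(.data$start))
  if (any(out$start > out$end)) {
    stop("overlapping or unsorted exons within a transcript", call. = FALSE)
  }
  dplyr::select(out, "gene_id", "transcript_id", "contig",
                "start", "end", "strand")
}

# exonic sequence outside the CDS genomic span, split 5'/3' by strand
derive_utrs <- function(exons, cds) {
  empty <- tibble::tibble(gene_id = character(), transcript_id = character(),
                          contig = character(), start = integer(),
                          end = integer(), strand = character())
  if (nrow(cds) == 0L) return(list(utr5 = empty, utr3 = empty))
  span <- dplyr::summarise(
    dplyr::group_by(cds, .data$transcript_id),
    cds_start = min(.data$start), cds_end = max(.data$end),
    .groups = "drop"
  )
  ex <- dplyr::inner_join(exons, span, by = "transcript_id")
  left <- dplyr::transmute(
    dplyr::filter(ex, .data$start < .data$cds_start),
    gene_id = .data$gene_id, transcript_id = .data$transcript_id,
    contig = .data$contig, start = .data$start,
    end = pmin(.data$end, .data$cds_start), strand = .data$strand
  )
  right <- dplyr::transmute(
    dplyr::filter(ex, .data$end > .data$cds_end),
    gene_id = .data$gene_id, transcript_id = .data$transcript_id,
    contig = .data$contig, start = pmax(.data$start, .data$cds_end),
    end = .data$end, strand = .data$strand
  )
  # genomic-left of the CDS is the 5' side on '+', the 3' side on '-'
  utr5 <- dplyr::bind_rows(dplyr::filter(left, .data$strand == "+"),
                           dplyr::filter(right, .data$strand == "-"))
  utr3 <- dplyr::bind_rows(dplyr::filter(right, .data$strand == "+"),
                           dplyr::filter(left, .data$strand == "-"))
  list(utr5 = tibble::as_tibble(utr5), utr3 = tibble::as_tibble(utr3))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts, ", nrow(x$exons), " exons, ",
      nrow(x$introns), " introns",
      if (nrow(x$cds) > 0L) paste0(", ", nrow(x$cds), " CDS") else "",
      "\n", sep = "")
  invisible(x)
}

#' Write a genome annotation back to GTF
#'
#' Emits gene, transcript, exon and CDS features with `gene_id` /
#' `transcript_id` attributes, converting internal 0-based half-open
#' coordinates back to GTF 1-based closed. A write/read cycle preserves
#' coordinates exactly.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  fmt <- function(df, type, attrs) {
    if (nrow(df) == 0L) return(character(0))
    sprintf("%s\tsplicebind\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$contig, type, df$start + 1L, df$end, df$strand, attrs)
  }
  g <- annotation$genes
  tr <- annotation$transcripts
  ex <- dplyr::arrange(annotation$exons, .data$contig, .data$transcript_id,
                       .data$start)
  cds <- annotation$cds
  lines <- c(
    fmt(g, "gene", sprintf('gene_id "%s";', g$gene_id)),
    fmt(tr, "transcript",
        sprintf('gene_id "%s"; transcript_id "%s";',
                tr$gene_id, tr$transcript_id)),
    fmt(ex, "exon",
        sprintf('gene_id "%s"; transcript_id "%s";',
                ex$gene_id, ex$transcript_id)),
    fmt(cds, "CDS",
        sprintf('gene_id "%s"; transcript_id "%s";',
                cds$gene_id, cds$transcript_id))
  )
  writeLines(lines, path)
  invisible(path)
}
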