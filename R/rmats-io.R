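#' @keywords internal
rmats_coord_cols <- function(event_type) {
  switch(event_type,
    SE = c(exon1_start = "exonStart_0base", exon1_end = "exonEnd",
           upstream_start = "upstreamES", upstream_end = "upstreamEE",
           downstream_start = "downstreamES", downstream_end = "downstreamEE"),
    MXE = c(exon1_start = "1stExonStart_0base", exon1_end = "1stExonEnd",
            exon2_start = "2ndExonStart_0base", exon2_end = "2ndExonEnd",
            upstream_start = "upstreamES", upstream_end = "upstreamEE",
            downstream_start = "downstreamES", downstream_end = "downstreamEE"),
    A5SS = c(exon1_start = "longExonStart_0base", exon1_end = "longExonEnd",
             upstream_start = "shortES", upstream_end = "shortEE",
             downstream_start = "flankingES", downstream_end = "flankingEE"),
    A3SS = c(exon1_start = "longExonStart_0base", exon1_end = "longExonEnd",
             upstream_start = "shortES", upstream_end = "shortEE",
             downstream_start = "flankingES", downstream_end = "flankingEE"),
    RI = c(exon1_start = "riExonStart_0base", exon1_end = "riExonEnd",
           upstream_start = "upstreamES", upstream_end = "upstreamEE",
           downstream_start = "downstreamES", downstream_end = "downstreamEE"),
    stop("unknown event type: ", event_type, call. = FALSE)
  )
}

parse_num_list <- function(x, col, allow_na = FALSE) {
  lapply(seq_along(x), function(i) {
    parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    bad <- is.na(v) & parts != "NA"
    if (any(bad)) {
      stop("non-numeric value '", parts[bad][1], "' in column ", col,
           ", row ", i, call. = FALSE)
    }
    if (!allow_na && anyNA(v)) {
      stop("missing value in column ", col, ", row ", i, call. = FALSE)
    }
    v
  })
}

#' Read an rMATS v4 differential-splicing table
#'
#' Parses the tab-separated `*.MATS.JCEC.txt` dialect for one event type.
#' Replicate junction counts (`IJC_SAMPLE_1`, ...) and PSI values
#' (`IncLevel1/2`) are comma-separated per row and become list-columns of
#' numeric vectors; `"NA"` PSI entries are preserved as missing.
#' Coordinates (`exonStart_0base` etc.) are already 0-based half-open and
#' are kept unchanged.
#'
#' @param path Path to the table.
#' @param event_type One of `"SE"`, `"MXE"`, `"A5SS"`, `"A3SS"`, `"RI"`.
#' @return A tibble with one row per event: identifiers, coordinates
#'   (`exon1_*` is the regulated/long/retained exon; `exon2_*` the MXE
#'   second exon), list-columns `ijc_1`, `sjc_1`, `ijc_2`, `sjc_2`,
#'   `inc_level_1`, `inc_level_2`, and `dpsi` (`IncLevelDifference`),
#'   `pvalue`, `fdr`, `event_type`.
#' @export
read_rmats_table <- function(path,
                             event_type = c("SE", "MXE", "A5SS", "A3SS",
                                            "RI")) {
  event_type <- match.arg(event_type)
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, name_repair = "minimal")
  raw <- raw[, !duplicated(names(raw)), drop = FALSE]  # rMATS repeats 'ID'
  cmap <- rmats_coord_cols(event_type)
  required <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
                unname(cmap),
                "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                "SJC_SAMPLE_2", "PValue", "FDR", "IncLevel1", "IncLevel2",
                "IncLevelDifference")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("rMATS ", event_type, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev <- tibble::tibble(
    event_id = raw$ID,
    gene_id = raw$GeneID,
    gene_symbol = raw$geneSymbol,
    contig = raw$chr,
    strand = raw$strand,
    event_type = event_type
  )
  for (nm in names(cmap)) ev[[nm]] <- as.integer(raw[[cmap[[nm]]]])
  if (!"exon2_start" %in% names(ev)) {
    ev$exon2_start <- NA_integer_
    ev$exon2_end <- NA_integer_
  }
  ev$ijc_1 <- parse_num_list(raw$IJC_SAMPLE_1, "IJC_SAMPLE_1")
  ev$sjc_1 <- parse_num_list(raw$SJC_SAMPLE_1, "SJC_SAMPLE_1")
  ev$ijc_2 <- parse_num_list(raw$IJC_SAMPLE_2, "IJC_SAMPLE_2")
  ev$sjc_2 <- parse_num_list(raw$SJC_SAMPLE_2, "SJC_SAMPLE_2")
  ev$inc_level_1 <- parse_num_list(raw$IncLevel1, "IncLevel1",
                                   allow_na = TRUE)
  ev$inc_level_2 <- parse_num_list(raw$IncLevel2, "IncLevel2",
                                   allow_na = TRUE)
  ev$dpsi <- as.numeric(raw$IncLevelDifference)
  ev$pvalue <- as.numeric(raw$PValue)
  ev$fdr <- as.numeric(raw$FDR)
  validate_rmats_events(ev)
  ev
}

validate_rmats_events <- function(ev) {
  psi <- unlist(c(ev$inc_level_1, ev$inc_level_2))
  psi <- psi[!is.na(psi)]
  if (length(psi) > 0L && (any(psi < 0) || any(psi > 1))) {
    stop("PSI value outside [0, 1]", call. = FALSE)
  }
  if (any(ev$exon1_start >= ev$exon1_end, na.rm = TRUE)) {
    stop("event with exon start >= end", call. = FALSE)
  }
  # flanking exons must sit on opposite genomic sides of the regulated exon
  lo <- pmin(ev$upstream_start, ev$downstream_start)
  hi <- pmax(ev$upstream_end, ev$downstream_end)
  bad <- !is.na(lo) & !(lo <= ev$exon1_start & hi >= ev$exon1_end)
  if (any(bad)) {
    stop("flanking exons do not bracket the regulated exon (",
         sum(bad), " event(s))", call. = FALSE)
  }
  # dpsi should equal mean(PSI_1) - mean(PSI_2) when both are present
  m1 <- vapply(ev$inc_level_1, function(v) mean(v, na.rm = TRUE), numeric(1))
  m2 <- vapply(ev$inc_level_2, function(v) mean(v, na.rm = TRUE), numeric(1))
  ok <- is.finite(m1) & is.finite(m2) & !is.na(ev$dpsi)
  off <- ok & abs((m1 - m2) - ev$dpsi) > 0.011  # rMATS rounds to 3 digits
  if (any(off)) {
    warning(sum(off), " event(s) with IncLevelDifference inconsistent ",
            "with replicate PSI means", call. = FALSE)
  }
  invisible(ev)
}

fmt_num_list <- function(x, digits = 3) {
  vapply(x, function(v) {
    s <- ifelse(is.na(v), "NA", formatC(round(v, digits), format = "g",
                                        digits = 8))
    paste(s, collapse = ",")
  }, character(1))
}

#' Write events back to the rMATS v4 table dialect
#'
#' Inverse of [read_rmats_table()] for a single event type (used by the
#' synthetic-data generator). Junction counts are written as
#' comma-separated integers, PSI values rounded to 3 decimals as rMATS
#' prints them.
#'
#' @param events Event tibble in the [read_rmats_table()] layout (one
#'   event type only).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmats_table <- function(events, path) {
  et <- unique(events$event_type)
  stopifnot(length(et) == 1L)
  cmap <- rmats_coord_cols(et)
  out <- list(ID = events$event_id, GeneID = events$gene_id,
              geneSymbol = events$gene_symbol, chr = events$contig,
              strand = events$strand)
  for (nm in names(cmap)) out[[cmap[[nm]]]] <- events[[nm]]
  out$IJC_SAMPLE_1 <- fmt_num_list(events$ijc_1, 0)
  out$SJC_SAMPLE_1 <- fmt_num_list(events$sjc_1, 0)
  out$IJC_SAMPLE_2 <- fmt_num_list(events$ijc_2, 0)
  out$SJC_SAMPLE_2 <- fmt_num_list(events$sjc_2, 0)
  out$IncFormLen <- rep(100L, nrow(events))
  out$SkipFormLen <- rep(50L, nrow(events))
  out$PValue <- formatC(events$pvalue, format = "g", digits = 12)
  out$FDR <- formatC(events$fdr, format = "g", digits = 12)
  out$IncLevel1 <- fmt_num_list(events$inc_level_1)
  out$IncLevel2 <- fmt_num_list(events$inc_level_2)
  out$IncLevelDifference <- formatC(round(events$dpsi, 3), format = "g",
                                    digits = 8)
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}
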