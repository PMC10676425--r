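#' Peak-file dialect description
#'
#' CLIP peak callers emit BED6-plus files whose extra columns differ between
#' pipelines; a dialect maps the 1-based column indices of the log2
#' fold-change over the size-matched input and of the peak p-value.
#'
#' @param log2fc_col 1-based column index carrying log2(IP/input).
#' @param pvalue_col 1-based column index carrying the peak p-value.
#' @return A `peak_dialect` list.
#' @export
peak_dialect <- function(log2fc_col = 7L, pvalue_col = 8L) {
  stopifnot(log2fc_col >= 7L, pvalue_col >= 7L, log2fc_col != pvalue_col)
  structure(list(log2fc_col = as.integer(log2fc_col),
                 pvalue_col = as.integer(pvalue_col)),
            class = "peak_dialect")
}

#' Read CLIP peaks from a BED6+ file
#'
#' Coordinates are BED-native 0-based half-open and are kept that way
#' internally. Fold enrichment is derived as `2^log2fc`.
#'
#' @param path Path to a tab-separated BED6+ file (no header).
#' @param dialect A [peak_dialect()] mapping the extra columns.
#' @return Tibble of peaks: `contig`, `start`, `end`, `peak_id`, `strand`,
#'   `log2fc`, `fold_enrichment`, `pvalue`, `width`, in file order.
#' @export
read_peak_file <- function(path, dialect = peak_dialect()) {
  stopifnot(file.exists(path), inherits(dialect, "peak_dialect"))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- max(6L, dialect$log2fc_col, dialect$pvalue_col)
  if (ncol(raw) < need) {
    stop("peak file has ", ncol(raw), " columns; dialect needs ", need,
         call. = FALSE)
  }
  pk <- tibble::tibble(
    contig = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    peak_id = raw[[4]],
    strand = raw[[6]],
    log2fc = as.numeric(raw[[dialect$log2fc_col]]),
    pvalue = as.numeric(raw[[dialect$pvalue_col]])
  )
  if (anyNA(pk$start) || anyNA(pk$end) || anyNA(pk$log2fc) ||
      anyNA(pk$pvalue)) {
    stop("non-numeric coordinate, log2fc, or p-value in peak file",
         call. = FALSE)
  }
  if (!all(pk$strand %in% c("+", "-"))) {
    stop("peak strand must be '+' or '-'", call. = FALSE)
  }
  if (any(pk$end <= pk$start)) stop("peak with end <= start", call. = FALSE)
  if (any(pk$pvalue <= 0 | pk$pvalue > 1)) {
    stop("peak p-value outside (0, 1]", call. = FALSE)
  }
  pk$fold_enrichment <- 2^pk$log2fc
  pk$width <- pk$end - pk$start
  pk
}

#' Write peaks as BED6+2 (log2fc, p-value)
#'
#' @param peaks Peak tibble as returned by [read_peak_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_file <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t.\t%s\t%s\t%s",
                   peaks$contig, peaks$start, peaks$end, peaks$peak_id,
                   peaks$strand,
                   formatC(peaks$log2fc, format = "g", digits = 8),
                   formatC(peaks$pvalue, format = "g", digits = 8))
  writeLines(lines, path)
  invisible(path)
}
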