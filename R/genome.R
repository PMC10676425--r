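#' Read a genome FASTA file
#'
#' Loads a (small) genome into memory as a named set of contig sequences.
#' Sequences are upper-cased and RNA `U` is normalized to DNA `T`, so all
#' downstream k-mer and flank operations work on the DNA alphabet
#' `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_seq` object: a named character vector of contig
#'   sequences with one element per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgu", ">c2", "TTTT"), fa)
#' g <- read_fasta(fa)
#' unname(g["c1"])
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("uU", "tT", as.character(ss))
  seqs <- toupper(seqs)
  names(seqs) <- nm
  structure(seqs, class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x), " contig(s), ",
      format(sum(nchar(x)), big.mark = ","), " nt total\n", sep = "")
  ln <- contig_lengths(x)
  for (i in seq_len(min(6L, length(ln)))) {
    cat("  ", names(ln)[i], ": ", ln[i], " nt\n", sep = "")
  }
  if (length(ln) > 6L) cat("  ...\n")
  invisible(x)
}

#' Contig lengths of a genome
#'
#' @param genome A `genome_seq` object.
#' @return Named integer vector of contig lengths in nt.
#' @export
contig_lengths <- function(genome) {
  vapply(unclass(genome), nchar, integer(1))
}

#' Fetch genomic sequence for 0-based half-open intervals
#'
#' @param genome A `genome_seq`.
#' @param contig Contig name(s).
#' @param start,end 0-based half-open interval bounds (vectorized).
#' @param strand `"+"` or `"-"`; minus-strand intervals are
#'   reverse-complemented so the result is always the sense-strand sequence.
#' @param truncate If `TRUE` (default) intervals poking past contig bounds
#'   are clipped; if `FALSE` that is an error.
#' @return Character vector of sequences.
#' @export
get_sequence <- function(genome, contig, start, end, strand = "+",
                         truncate = TRUE) {
  n <- max(length(contig), length(start), length(end), length(strand))
  contig <- rep_len(contig, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  lens <- contig_lengths(genome)
  if (!all(contig %in% names(lens))) {
    stop("unknown contig(s): ",
         paste(setdiff(unique(contig), names(lens)), collapse = ", "),
         call. = FALSE)
  }
  cl <- unname(lens[contig])
  if (any(start > end)) stop("interval start > end", call. = FALSE)
  s <- pmax(start, 0L); e <- pmin(end, cl)
  if (!truncate && (any(start < 0L) || any(end > cl))) {
    stop("interval outside contig bounds", call. = FALSE)
  }
  out <- character(n)
  keep <- s < e
  out[keep] <- substr(unclass(genome)[contig[keep]], s[keep] + 1L, e[keep])
  neg <- keep & strand == "-"
  out[neg] <- revcomp(out[neg])
  out
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector over `{A,C,G,T,N}` (lower case accepted).
#' @return Reverse-complemented upper-case strings.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x)))
  )
  unname(out)
}

#' Extract the intronic flank of an exon in transcribed orientation
#'
#' Returns the sense-strand sequence immediately up- or downstream of an
#' exon. For a `+` strand exon `[start, end)`, the downstream flank is
#' `[end, end + length)`; on the `-` strand it is the reverse complement of
#' `[start - length, start)`. Flanks running off the contig are truncated
#' and flagged.
#'
#' @param genome A `genome_seq`.
#' @param exons A data frame with columns `contig`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param side `"upstream"` or `"downstream"`, in transcript orientation.
#' @param length Flank length in nt (default 200, the flank width used for
#'   the 5-mer scans).
#' @return A tibble: the input rows plus `flank_seq`, `flank_start`,
#'   `flank_end` (genomic, 0-based half-open) and `truncated`.
#' @export
extract_flank_sequence <- function(genome, exons,
                                   side = c("downstream", "upstream"),
                                   length = 200L) {
  side <- match.arg(side)
  stopifnot(length >= 1L)
  ex <- tibble::as_tibble(exons)
  req <- c("contig", "start", "end", "strand")
  if (!all(req %in% names(ex))) {
    stop("exons must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  lens <- contig_lengths(genome)
  if (!all(ex$contig %in% names(lens))) {
    stop("exon contig(s) not in genome", call. = FALSE)
  }
  cl <- unname(lens[ex$contig])
  if (any(ex$start < 0L) || any(ex$end > cl) || any(ex$start >= ex$end)) {
    stop("exon interval outside contig bounds or empty", call. = FALSE)
  }
  # genomically-after-exon flank <=> (downstream on +) or (upstream on -)
  after <- (ex$strand == "+") == (side == "downstream")
  fs <- ifelse(after, ex$end, ex$start - length)
  fe <- ifelse(after, ex$end + length, ex$start)
  fs_c <- pmax(fs, 0L)
  fe_c <- pmin(fe, cl)
  ex$flank_start <- as.integer(fs_c)
  ex$flank_end <- as.integer(fe_c)
  ex$truncated <- (fs < 0L) | (fe > cl)
  ex$flank_seq <- get_sequence(genome, ex$contig, fs_c, fe_c, ex$strand)
  ex
}
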