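all_kmers <- function(k) {
  mkAllStrings <- Biostrings::mkAllStrings
  mkAllStrings(c("A", "C", "G", "T"), k)
}

#' Count k-mers with a step-1 sliding window
#'
#' Counts every window of width `k` across a set of sense-strand sequences
#' (overlapping windows all count). Windows containing a non-ACGT letter
#' (e.g. `N`) are skipped and excluded from the window total. Input `U` is
#' normalized to `T`.
#'
#' @param sequences Character vector of DNA/RNA sequences.
#' @param k Word size, 1 to 8.
#' @return List with `counts` (named integer vector over all `4^k` k-mers,
#'   zeros included) and `total` (number of counted windows;
#'   `sum(counts) == total`).
#' @export
count_kmers_sliding <- function(sequences, k = 5L) {
  if (!is.numeric(k) || k < 1L || k > 8L) {
    stop("k must be between 1 and 8", call. = FALSE)
  }
  k <- as.integer(k)
  seqs <- toupper(chartr("uU", "tT", sequences))
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) {
    z <- stats::setNames(integer(4^k), all_kmers(k))
    return(list(counts = z, total = 0L))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(ss, width = k, step = 1L)
  counts <- if (is.matrix(m)) colSums(m) else m
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, total = sum(counts))
}

#' Binomial k-mer enrichment of foreground vs background sequence
#'
#' For every k-mer, compares its sliding-window frequency in a foreground
#' sequence set (e.g. intronic flanks of splicing-sensitive exons) against
#' a background set (flanks of insensitive/constitutive exons of the same
#' side and length). The background per-window probability is
#' pseudocounted, `bg_freq = (bg_count + pc) / (bg_total + pc * 4^k)`; the
#' one-sided (enrichment) p-value is the binomial upper tail
#' `P(X >= fg_count)` for `X ~ Binomial(fg_total, bg_freq)`; Bonferroni
#' correction multiplies by the `4^k` tests, capped at 1. Depletion shows
#' up as enrichment < 1 without a second test.
#'
#' @param fg_sequences,bg_sequences Character vectors of sequences (both
#'   non-empty in windows).
#' @param k Word size (default 5).
#' @param pseudocount Added to each background count (default 1).
#' @return A `kmer_enrichment` tibble sorted by `p_adj` then decreasing
#'   enrichment: `kmer`, `fg_count`, `fg_total`, `bg_count`, `bg_freq`,
#'   `enrichment`, `log2_enrichment`, `p_raw`, `p_adj`.
#' @export
kmer_enrichment_test <- function(fg_sequences, bg_sequences, k = 5L,
                                 pseudocount = 1) {
  fg <- count_kmers_sliding(fg_sequences, k)
  bg <- count_kmers_sliding(bg_sequences, k)
  if (fg$total == 0L) stop("no foreground windows", call. = FALSE)
  if (bg$total == 0L) stop("no background windows", call. = FALSE)
  n_tests <- 4^as.integer(k)
  bg_freq <- (bg$counts + pseudocount) / (bg$total + pseudocount * n_tests)
  p_raw <- stats::pbinom(fg$counts - 1L, fg$total, bg_freq,
                         lower.tail = FALSE)
  enr <- (fg$counts / fg$total) / bg_freq
  out <- tibble::tibble(
    kmer = names(fg$counts),
    fg_count = as.integer(fg$counts),
    fg_total = fg$total,
    bg_count = as.integer(bg$counts),
    bg_freq = as.numeric(bg_freq),
    enrichment = as.numeric(enr),
    log2_enrichment = log2(as.numeric(enr)),
    p_raw = as.numeric(p_raw),
    p_adj = pmin(1, n_tests * as.numeric(p_raw))
  )
  out <- dplyr::arrange(out, .data$p_adj, dplyr::desc(.data$enrichment))
  class(out) <- c("kmer_enrichment", class(out))
  attr(out, "k") <- as.integer(k)
  attr(out, "pseudocount") <- pseudocount
  out
}

# first-order Markov resample of one sequence: preserves the dinucleotide
# transition structure in expectation
markov_shuffle_seq <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  bases <- c("A", "C", "G", "T")
  trans <- matrix(0, 4L, 4L, dimnames = list(bases, bases))
  from <- ch[-n]; to <- ch[-1L]
  ok <- from %in% bases & to %in% bases
  tt <- table(factor(from[ok], bases), factor(to[ok], bases))
  trans <- trans + as.matrix(tt)
  out <- character(n)
  out[1L] <- if (ch[1L] %in% bases) ch[1L] else sample(bases, 1L)
  for (i in 2:n) {
    w <- trans[out[i - 1L], ]
    if (sum(w) == 0) w <- rep(1, 4L)
    out[i] <- sample(bases, 1L, prob = w)
  }
  paste(out, collapse = "")
}

#' K-mer enrichment under CLIP peaks
#'
#' Foreground is the sense-strand sequence under each peak. Background is
#' built per the chosen scheme: `"flank-shift"` (default) takes a
#' same-width region shifted two peak-widths downstream on the same strand,
#' clipped to the containing gene (or contig when no annotation is given);
#' `"dinucleotide-shuffle"` resamples each peak sequence through its own
#' dinucleotide transition chain. Enrichment statistics are the same
#' binomial/Bonferroni machinery as [kmer_enrichment_test()], over `4^k`
#' tests.
#'
#' @param peaks Peak tibble.
#' @param genome A `genome_seq`.
#' @param annotation Optional `genome_annotation` used to clip shifted
#'   backgrounds to gene bounds.
#' @param k Word size (default 6).
#' @param background `"flank-shift"` or `"dinucleotide-shuffle"`.
#' @param seed Integer seed for the shuffle scheme (ignored by flank-shift).
#' @param pseudocount Passed to [kmer_enrichment_test()].
#' @return A `kmer_enrichment` tibble.
#' @export
peak_kmer_enrichment <- function(peaks, genome, annotation = NULL, k = 6L,
                                 background = c("flank-shift",
                                                "dinucleotide-shuffle"),
                                 seed = 1L, pseudocount = 1) {
  background <- match.arg(background)
  pk <- tibble::as_tibble(peaks)
  if (nrow(pk) == 0L) stop("no peaks", call. = FALSE)
  fg <- get_sequence(genome, pk$contig, pk$start, pk$end, pk$strand)
  if (background == "dinucleotide-shuffle") {
    bg <- withr::with_seed(seed, vapply(fg, markov_shuffle_seq,
                                        character(1), USE.NAMES = FALSE))
  } else {
    w <- pk$end - pk$start
    shift <- ifelse(pk$strand == "+", 2L * w, -2L * w)
    bs <- pk$start + shift
    be <- pk$end + shift
    lo <- rep(0L, nrow(pk))
    hi <- unname(contig_lengths(genome)[pk$contig])
    if (!is.null(annotation)) {
      hits <- assign_peaks_to_genes(pk, annotation)$assignments
      hits <- hits[!duplicated(hits$peak_id), , drop = FALSE]
      g <- annotation$genes
      idx <- match(pk$peak_id, hits$peak_id)
      gi <- match(hits$gene_id[idx], g$gene_id)
      lo <- ifelse(is.na(gi), lo, g$start[gi])
      hi <- ifelse(is.na(gi), hi, g$end[gi])
    }
    bs_c <- pmax(bs, lo); be_c <- pmin(be, hi)
    keep <- be_c - bs_c >= k
    if (!any(keep)) {
      stop("all shifted background regions fall out of bounds",
           call. = FALSE)
    }
    bg <- get_sequence(genome, pk$contig[keep], bs_c[keep], be_c[keep],
                       pk$strand[keep])
  }
  kmer_enrichment_test(fg, bg, k = k, pseudocount = pseudocount)
}

#' K-mer enrichment in the regulatory-side flanks of sensitive exons
#'
#' Pools, per the position-dependent binding model, the intronic flank on
#' the regulatory side of each sensitive exon — downstream for exons the
#' RBP promotes (included class), upstream for exons it represses (skipped
#' class) — as foreground, against the union of the same two flank sides
#' of insensitive exons as background, and runs
#' [kmer_enrichment_test()].
#'
#' @param genome A `genome_seq`.
#' @param sensitive_events Significant event tibble with a `direction`
#'   column (from [filter_significant()]).
#' @param insensitive_events Insensitive event tibble (from
#'   [select_insensitive()]).
#' @param k Word size (default 5).
#' @param flank_length Flank length in nt (default 200).
#' @param pseudocount Passed through.
#' @return A `kmer_enrichment` tibble.
#' @export
regulatory_flank_kmer_test <- function(genome, sensitive_events,
                                       insensitive_events, k = 5L,
                                       flank_length = 200L,
                                       pseudocount = 1) {
  ev <- tibble::as_tibble(sensitive_events)
  ins <- tibble::as_tibble(insensitive_events)
  exon_tab <- function(e) {
    tibble::tibble(contig = e$contig, start = e$exon1_start,
                   end = e$exon1_end, strand = e$strand)
  }
  fg <- c(
    extract_flank_sequence(genome,
                           exon_tab(ev[ev$direction == "included", ]),
                           side = "downstream",
                           length = flank_length)$flank_seq,
    extract_flank_sequence(genome,
                           exon_tab(ev[ev$direction == "skipped", ]),
                           side = "upstream",
                           length = flank_length)$flank_seq
  )
  bg <- c(
    extract_flank_sequence(genome, exon_tab(ins), side = "downstream",
                           length = flank_length)$flank_seq,
    extract_flank_sequence(genome, exon_tab(ins), side = "upstream",
                           length = flank_length)$flank_seq
  )
  kmer_enrichment_test(fg, bg, k = k, pseudocount = pseudocount)
}

#' Transliterate reported k-mers to the RNA alphabet for display
#'
#' @param kmer Character vector of DNA k-mers.
#' @return Same k-mers with `T` replaced by `U` (e.g. GCATG -> GCAUG).
#' @export
as_rna_kmer <- function(kmer) chartr("Tt", "Uu", kmer)
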