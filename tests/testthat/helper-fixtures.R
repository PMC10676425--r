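# in-code fixtures shared across test files

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# genome with two contigs; c1 carries a simple layout for flank tests
tiny_genome <- function() {
  fa <- write_tmp(c(
    ">c1",
    "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",  # 40 nt
    ">c2",
    "TTTTGGGGCCCCAAAA"                            # 16 nt
  ), ".fa")
  read_fasta(fa)
}

# one + strand gene (2 exons, CDS) and one - strand gene (3 exons)
tiny_gtf_lines <- function() {
  a <- 'gene_id "gA"; transcript_id "tA";'
  b <- 'gene_id "gB"; transcript_id "tB";'
  c(
    paste("c1\tx\tgene\t11\t100\t.\t+\t.", 'gene_id "gA";', sep = "\t"),
    paste("c1\tx\ttranscript\t11\t100\t.\t+\t.", a, sep = "\t"),
    paste("c1\tx\texon\t11\t30\t.\t+\t.", a, sep = "\t"),
    paste("c1\tx\texon\t61\t100\t.\t+\t.", a, sep = "\t"),
    paste("c1\tx\tCDS\t21\t30\t.\t+\t.", a, sep = "\t"),
    paste("c1\tx\tCDS\t61\t80\t.\t+\t.", a, sep = "\t"),
    paste("c2\tx\tgene\t101\t400\t.\t-\t.", 'gene_id "gB";', sep = "\t"),
    paste("c2\tx\ttranscript\t101\t400\t.\t-\t.", b, sep = "\t"),
    paste("c2\tx\texon\t101\t150\t.\t-\t.", b, sep = "\t"),
    paste("c2\tx\texon\t201\t250\t.\t-\t.", b, sep = "\t"),
    paste("c2\tx\texon\t301\t400\t.\t-\t.", b, sep = "\t")
  )
}

tiny_annotation <- function() {
  read_gtf(write_tmp(tiny_gtf_lines(), ".gtf"))
}

# build an event tibble from per-event scalar args; replicate vectors are
# lists of numeric vectors
make_events <- function(n, event_type = "SE", contig = "c1", strand = "+",
                        exon1_start = 1000L + 500L * seq_len(n),
                        exon1_end = exon1_start + 100L,
                        dpsi = rep(0.2, n), pvalue = rep(0.01, n),
                        fdr = rep(0.01, n),
                        ijc_1 = rep(list(c(10, 10)), n),
                        sjc_1 = rep(list(c(10, 10)), n),
                        ijc_2 = rep(list(c(10, 10)), n),
                        sjc_2 = rep(list(c(10, 10)), n),
                        gene_symbol = sprintf("g%02d", seq_len(n))) {
  tibble::tibble(
    event_id = as.character(seq_len(n)), gene_id = gene_symbol,
    gene_symbol = gene_symbol, contig = contig, strand = strand,
    event_type = event_type,
    exon1_start = as.integer(exon1_start),
    exon1_end = as.integer(exon1_end),
    exon2_start = NA_integer_, exon2_end = NA_integer_,
    upstream_start = as.integer(exon1_start - 300L),
    upstream_end = as.integer(exon1_start - 200L),
    downstream_start = as.integer(exon1_end + 200L),
    downstream_end = as.integer(exon1_end + 300L),
    ijc_1 = ijc_1, sjc_1 = sjc_1, ijc_2 = ijc_2, sjc_2 = sjc_2,
    inc_level_1 = rep(list(c(0.5, 0.5)), n),
    inc_level_2 = rep(list(c(0.5, 0.5)), n),
    dpsi = dpsi, pvalue = pvalue, fdr = fdr
  )
}

make_peaks <- function(contig, start, end, strand = "+",
                       log2fc = 2, pvalue = 1e-4) {
  n <- max(length(start), length(end))
  tibble::tibble(
    contig = rep_len(contig, n), start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    peak_id = sprintf("pk%03d", seq_len(n)),
    strand = rep_len(strand, n),
    log2fc = rep_len(log2fc, n),
    fold_enrichment = 2^rep_len(log2fc, n),
    pvalue = rep_len(pvalue, n),
    width = as.integer(rep_len(end, n) - rep_len(start, n))
  )
}

# exon tibble shorthand
make_exons <- function(start, end, contig = "c1", strand = "+") {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

# small, fast simulation config for tests that do not need the defaults
fast_sim_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 40L, seed = seed, ...)
}
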