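# position-by-position window oracle
oracle_count <- function(seqs, k) {
  counts <- integer(0)
  total <- 0L
  for (s in seqs) {
    s <- toupper(chartr("u", "t", s))
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      total <- total + 1L
      counts[w] <- if (w %in% names(counts)) counts[[w]] + 1L else 1L
    }
  }
  list(counts = counts, total = total)
}

test_that("sliding-window counting is exhaustive and overlap-aware", {
  r <- count_kmers_sliding("ACGTA", 5)
  expect_identical(unname(r$counts["ACGTA"]), 1L)
  expect_identical(r$total, 1L)
  r2 <- count_kmers_sliding("AAAAAA", 5)
  expect_identical(unname(r2$counts["AAAAA"]), 2L)
  expect_identical(r2$total, 2L)
  # windows containing N are skipped and excluded from the total
  r3 <- count_kmers_sliding("AANTT", 2)
  expect_identical(r3$total, 2L)
  expect_identical(unname(r3$counts[c("AA", "TT")]), c(1L, 1L))
  expect_error(count_kmers_sliding("ACGT", 0), "between")
  expect_error(count_kmers_sliding("ACGT", 9), "between")
})

test_that("counts equal the brute-force enumeration on random sequence", {
  seqs <- withr::with_seed(5, vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, character(1)))
  for (k in c(1L, 3L, 5L)) {
    got <- count_kmers_sliding(seqs, k)
    want <- oracle_count(seqs, k)
    expect_identical(got$total, want$total)
    expect_identical(sum(got$counts), got$total)
    for (w in names(want$counts)) {
      expect_identical(unname(got$counts[w]), want$counts[[w]])
    }
    expect_identical(sum(got$counts[setdiff(names(got$counts),
                                            names(want$counts))]), 0L)
  }
})

test_that("identical foreground and background is a null result", {
  seqs <- withr::with_seed(6, vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1)))
  ke <- kmer_enrichment_test(seqs, seqs, k = 3)
  expect_true(all(ke$p_adj == 1))
  present <- ke[ke$fg_count >= 5, ]
  expect_true(all(abs(present$enrichment - 1) < 0.15))
})

test_that("binomial p-values equal the closed-form tail sum", {
  # planted GCATG foreground in random context vs GCATG-free background
  withr::with_seed(61, {
    ctx <- function() paste(sample(c("A", "C", "T"), 10, TRUE),
                            collapse = "")
    fg <- vapply(1:20, function(i) paste0(ctx(), "GCATG", ctx()),
                 character(1))
    bg <- vapply(1:30, function(i) paste0(ctx(), ctx()), character(1))
  })
  ke <- kmer_enrichment_test(fg, bg, k = 5)
  expect_identical(ke$kmer[1], "GCATG")
  g <- ke[ke$kmer == "GCATG", ]
  # oracle: direct summation of the binomial upper tail
  p_direct <- sum(dbinom(g$fg_count:g$fg_total, g$fg_total, g$bg_freq))
  expect_equal(g$p_raw, p_direct, tolerance = 1e-12)
  expect_equal(g$p_adj, min(1, 1024 * p_direct), tolerance = 1e-12)

  # k = 1 case with an enumerable tail
  ke1 <- kmer_enrichment_test(rep("A", 10), rep("ACGT", 10), k = 1)
  a <- ke1[ke1$kmer == "A", ]
  p_want <- (11 / 44)^10          # bg_freq = (10+1)/(40+4); X >= 10 of 10
  expect_equal(a$bg_freq, 11 / 44)
  expect_equal(a$p_raw, p_want, tolerance = 1e-12)
})

test_that("swapping foreground and background inverts enrichment", {
  withr::with_seed(7, {
    fg <- vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
      character(1))
    bg <- vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
      character(1))
  })
  a <- kmer_enrichment_test(fg, bg, k = 3)
  b <- kmer_enrichment_test(bg, fg, k = 3)
  ab <- dplyr::inner_join(
    tibble::as_tibble(a)[, c("kmer", "fg_count", "enrichment")],
    tibble::as_tibble(b)[, c("kmer", "fg_count", "enrichment")],
    by = "kmer"
  )
  ab <- ab[ab$fg_count.x >= 5 & ab$fg_count.y >= 5, ]
  expect_gt(nrow(ab), 20L)
  expect_true(all(abs(log2(ab$enrichment.x) + log2(ab$enrichment.y)) <
                    0.35))
})

test_that("family-wise error is controlled under the null", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      fg <- vapply(1:20, function(i)
        paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
        character(1))
      bg <- vapply(1:40, function(i)
        paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
        character(1))
    })
    ke <- kmer_enrichment_test(fg, bg, k = 5)
    mean(ke$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(hits), 0.05)
})

test_that("peak k-mer enrichment recovers motifs under peaks", {
  # genome: 40 GCATG islands in random sequence, peaks centered on them
  withr::with_seed(8, {
    chunks <- vapply(1:40, function(i) {
      left <- paste(sample(c("A", "C", "T"), 48, TRUE), collapse = "")
      right <- paste(sample(c("A", "C", "T"), 47, TRUE), collapse = "")
      paste0(left, "GCATG", right)
    }, character(1))
  })
  g <- structure(c(c1 = paste(chunks, collapse = "")),
                 class = "genome_seq")
  starts <- (seq_len(40) - 1L) * 100L + 30L
  pk <- make_peaks("c1", starts, starts + 40L)
  ke <- peak_kmer_enrichment(pk, g, k = 6, background = "flank-shift")
  top <- ke$kmer[1:10]
  expect_true(any(grepl("GCATG", top)))
  expect_lt(ke$p_adj[grepl("GCATG", ke$kmer)][1], 0.05)

  # seeded shuffle background is reproducible
  k1 <- peak_kmer_enrichment(pk, g, k = 6,
                             background = "dinucleotide-shuffle", seed = 3)
  k2 <- peak_kmer_enrichment(pk, g, k = 6,
                             background = "dinucleotide-shuffle", seed = 3)
  expect_identical(k1, k2)
})

test_that("fully out-of-bounds shifted background raises an error", {
  g <- structure(c(c1 = strrep("ACGT", 30)), class = "genome_seq")
  # shifting +2 widths lands past the contig end
  pk <- make_peaks("c1", 60L, 110L)
  expect_error(peak_kmer_enrichment(pk, g, k = 6), "out of bounds")
})

test_that("tidiers summarize k-mer results", {
  ke <- kmer_enrichment_test(rep("TTTTTGCATGTTTTT", 5),
                             rep("AAAAAAAAAAAAAAA", 5), k = 5)
  td <- tidy(ke)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "kmer_enrichment"))
  gl <- glance(ke)
  expect_identical(gl$n_kmers, nrow(ke))
  expect_identical(gl$k, 5L)
  expect_identical(gl$top_kmer, ke$kmer[1])
})
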