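# independent row-scan oracle used against filter_significant /
# select_insensitive
oracle_filter <- function(ev, fdr_max, dpsi_min, min_reads) {
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    r1 <- sum(ev$ijc_1[[i]]) + sum(ev$sjc_1[[i]])
    r2 <- sum(ev$ijc_2[[i]]) + sum(ev$sjc_2[[i]])
    keep[i] <- !is.na(ev$fdr[i]) && ev$fdr[i] < fdr_max &&
      abs(ev$dpsi[i]) >= dpsi_min && (r1 >= min_reads || r2 >= min_reads)
  }
  ev$event_id[keep]
}

ten_row_fixture <- function() {
  make_events(
    10,
    fdr = c(0.04, 0.04, 0.2, 0.001, 0.04, NA, 0.049, 0.05, 0.01, 0.8),
    dpsi = c(0.02, 0.02, 0.5, 0.005, -0.06, 0.3, 0.03, 0.2, 0.049, 0.0),
    ijc_1 = list(c(10, 15), c(5, 4), c(30, 30), c(40, 0), c(10, 10),
                 c(50, 50), c(10, 10), c(10, 10), c(3, 3), c(10, 10)),
    sjc_1 = list(c(0, 0), c(5, 5), c(0, 0), c(0, 0), c(10, 10),
                 c(0, 0), c(10, 10), c(10, 10), c(3, 3), c(10, 10)),
    ijc_2 = list(c(0, 0), c(4, 5), c(1, 1), c(0, 0), c(0, 0),
                 c(0, 0), c(0, 0), c(0, 0), c(2, 2), c(0, 0)),
    sjc_2 = list(c(0, 0), c(0, 0), c(1, 1), c(0, 0), c(0, 0),
                 c(0, 0), c(0, 0), c(0, 0), c(2, 2), c(0, 0))
  )
}

test_that("filter_significant applies the FDR, dPSI, and read rules", {
  # fdr 0.04, dpsi +0.02, condition-1 reads 25 -> retained
  ev <- make_events(1, fdr = 0.04, dpsi = 0.02,
                    ijc_1 = list(c(10, 5)), sjc_1 = list(c(5, 5)),
                    ijc_2 = list(c(2, 2)), sjc_2 = list(c(2, 2)))
  expect_identical(nrow(filter_significant(ev)), 1L)
  # reads 19 and 18 -> dropped by the read floor
  ev2 <- make_events(1, fdr = 0.04, dpsi = 0.02,
                     ijc_1 = list(c(10, 5)), sjc_1 = list(c(2, 2)),
                     ijc_2 = list(c(9, 5)), sjc_2 = list(c(2, 2)))
  expect_identical(nrow(filter_significant(ev2)), 0L)
})

test_that("10-row fixture matches the brute-force row scan at both dPSI cuts", {
  ev <- ten_row_fixture()
  for (dp in c(0.01, 0.05)) {
    got <- suppressWarnings(filter_significant(ev, dpsi_min = dp))
    expect_setequal(got$event_id, oracle_filter(ev, 0.05, dp, 20))
  }
  expect_warning(filter_significant(ev), "missing FDR")
})

test_that("significant set is monotone in the dPSI threshold", {
  ev <- ten_row_fixture()
  strict <- suppressWarnings(filter_significant(ev, dpsi_min = 0.05))
  loose <- suppressWarnings(filter_significant(ev, dpsi_min = 0.01))
  expect_true(all(strict$event_id %in% loose$event_id))
})

test_that("direction labels follow the dPSI sign convention", {
  ev <- make_events(2, fdr = c(0.01, 0.01), dpsi = c(0.3, -0.3),
                    ijc_1 = rep(list(c(20, 20)), 2),
                    sjc_1 = rep(list(c(20, 20)), 2))
  sig <- filter_significant(ev)
  expect_identical(sig$direction, c("included", "skipped"))
})

test_that("insensitive set is disjoint from significant and respects rules", {
  ev <- ten_row_fixture()
  sig <- suppressWarnings(filter_significant(ev, dpsi_min = 0.01))
  ins <- select_insensitive(ev)
  expect_length(intersect(sig$event_id, ins$event_id), 0L)
  # events at FDR exactly 0.05 fall in neither set
  expect_false("8" %in% c(sig$event_id, ins$event_id))
  # oracle: fdr > 0.05 and read support
  manual <- ev$event_id[!is.na(ev$fdr) & ev$fdr > 0.05 &
                          vapply(seq_len(nrow(ev)), function(i) {
                            sum(ev$ijc_1[[i]], ev$sjc_1[[i]]) >= 20 ||
                              sum(ev$ijc_2[[i]], ev$sjc_2[[i]]) >= 20
                          }, logical(1))]
  expect_setequal(ins$event_id, manual)
  expect_error(select_insensitive(make_events(2, fdr = c(0.01, 0.02))),
               "insensitive")
})

test_that("gene-level intersections match the 8-region enumeration oracle", {
  expect_error(intersect_gene_level(list(a = "x", a = "y")), "unique")
  cmp <- intersect_gene_level(list(s1 = c("a", "b"), s2 = "c"))
  expect_length(cmp$common, 0L)
  cmp2 <- intersect_gene_level(list(s1 = c("a", "b", "c"),
                                    s2 = c("b", "c", "d"),
                                    s3 = c("c", "e")))
  expect_identical(cmp2$common, "C")

  withr::with_seed(42, {
    pool <- sprintf("g%02d", 1:30)
    sets <- list(A = sample(pool, 12), B = sample(pool, 15),
                 C = sample(pool, 8))
  })
  cmp3 <- intersect_gene_level(sets)
  # oracle: tabulate membership of every gene over the 7 regions
  genes <- unique(toupper(unlist(sets)))
  memb <- sapply(sets, function(s) genes %in% toupper(s))
  for (i in seq_len(nrow(cmp3$regions))) {
    parts <- strsplit(cmp3$regions$region[i], "+", fixed = TRUE)[[1]]
    inc <- colnames(memb) %in% parts
    n_oracle <- sum(apply(memb, 1, function(m) {
      all(m[inc]) && !any(m[!inc])
    }))
    expect_identical(cmp3$regions$n[i], n_oracle)
  }
  # region counts cover every gene exactly once
  expect_identical(sum(cmp3$regions$n), length(genes))
})

test_that("gene intersections ignore event order, duplicates, and case", {
  a <- c("Snap25", "SNAP25", "stxbp1")
  b <- c("snap25", "Syt7")
  cmp <- intersect_gene_level(list(x = a, y = b))
  expect_identical(cmp$common, "SNAP25")
  cmp_rev <- intersect_gene_level(list(x = rev(a), y = b))
  expect_identical(cmp_rev$regions, cmp$regions)
})

test_that("event-level matching is exact on type, strand, and coordinates", {
  a <- make_events(3, dpsi = c(0.2, -0.3, 0.1))
  b <- a
  b$dpsi <- c(0.4, 0.3, -0.2)
  m <- intersect_event_level(a, b)
  expect_identical(nrow(m), 3L)
  expect_identical(m$concordant, c(TRUE, FALSE, FALSE))
  # type mismatch at the same locus -> no match
  b2 <- a; b2$event_type <- "MXE"
  expect_identical(nrow(intersect_event_level(a, b2)), 0L)
  # 1-nt shift -> no match
  b3 <- a; b3$exon1_start <- b3$exon1_start + 1L
  expect_identical(nrow(intersect_event_level(a, b3)), 0L)
})

test_that("concordance matrix marks non-significant datasets as missing", {
  a <- make_events(3, dpsi = c(0.2, -0.3, 0.1))
  b <- a[1:2, ]; b$dpsi <- c(0.25, -0.2)
  c3 <- a[1, ]; c3$dpsi <- 0.3
  mat <- dpsi_concordance_matrix(list(d1 = a, d2 = b, d3 = c3))
  expect_identical(nrow(mat), 2L)  # events shared by >= 2 datasets
  row1 <- mat[mat$key == splicebind:::event_match_key(a[1, ]), ]
  expect_false(anyNA(row1[, c("d1", "d2", "d3")]))
  row2 <- mat[mat$key == splicebind:::event_match_key(a[2, ]), ]
  expect_true(is.na(row2$d3))
})

test_that("replicated datasets from one truth agree in dPSI sign", {
  cfg1 <- fast_sim_config(seed = 21)
  sim <- simulate_genome_annotation(cfg1)
  cfg2 <- fast_sim_config(seed = 22)
  t1 <- simulate_splicing_counts(sim$truth, cfg1)$SE
  t2 <- simulate_splicing_counts(sim$truth, cfg2)$SE
  s1 <- filter_significant(t1, dpsi_min = 0.05)
  s2 <- filter_significant(t2, dpsi_min = 0.05)
  m <- intersect_event_level(s1, s2)
  expect_gt(nrow(m), 3L)
  expect_gte(mean(m$concordant), 0.9)
})

test_that("candidate RBP screen applies floor, significance, and centering", {
  tb <- tibble::tibble(
    gene = sprintf("r%02d", 1:12),
    mean_1 = c(2000, 900, 1400, 3000, 1600, 200, 5000, 1800, 1550, 100,
               2500, 1490),
    mean_2 = c(900, 2000, 1400, 2500, 100, 1700, 4000, 1900, 1600, 90,
               200, 1505),
    padj = c(0.01, 0.02, 0.01, 0.2, 0.001, 0.04, 0.03, NA, 0.049, 0.01,
             0.004, 0.06)
  )
  scr <- candidate_rbp_screen(tb, tb$gene)
  # oracle: manual tally
  keep <- pmax(tb$mean_1, tb$mean_2) > 1500 & !is.na(tb$padj) &
    tb$padj < 0.05
  expect_setequal(scr$candidates$gene, tb$gene[keep])
  up <- tb$mean_2[keep] > tb$mean_1[keep]
  expect_identical(sum(scr$candidates$direction == "up"), sum(up))
  expect_identical(sum(scr$candidates$direction == "down"), sum(!up))
  expect_true(all(abs(rowMeans(scr$centered)) < 1e-9))
  # floor excludes a 1400/1400 gene even when significant
  expect_false("r03" %in% scr$candidates$gene)
  expect_error(candidate_rbp_screen(tb, character(0)), "empty")
})
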