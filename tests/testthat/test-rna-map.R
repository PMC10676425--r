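test_that("metacoordinates follow the strand-aware sign convention", {
  ex <- make_exons(100L, 200L)
  # + strand, midpoint 225 -> downstream +25
  pr <- peak_metacoordinate(make_peaks("c1", 220L, 231L), ex, 2000L)
  expect_identical(pr$side, "downstream")
  expect_identical(pr$pos, 25L)
  # same genomic layout on '-': midpoint 225 is upstream at -25
  exm <- make_exons(100L, 200L, strand = "-")
  prm <- peak_metacoordinate(make_peaks("c1", 220L, 231L, strand = "-"),
                             exm, 2000L)
  expect_identical(prm$side, "upstream")
  expect_identical(prm$pos, -25L)
  # midpoint inside the exon -> side exon, pos 0
  pin <- peak_metacoordinate(make_peaks("c1", 145L, 156L), ex, 2000L)
  expect_identical(pin$side, "exon")
  expect_identical(pin$pos, 0L)
  # strand mismatch yields no pair, not an error
  none <- peak_metacoordinate(make_peaks("c1", 220L, 231L,
                                         strand = "-"), ex, 2000L)
  expect_identical(nrow(none), 0L)
  # beyond the window yields no pair
  far <- peak_metacoordinate(make_peaks("c1", 2500L, 2511L), ex, 300L)
  expect_identical(nrow(far), 0L)
})

test_that("profiles bin each in-window pair exactly once", {
  params <- rna_map_params(window = 300L, bin_width = 50L,
                           n_bootstrap = 10L)
  ex <- make_exons(1000L, 1100L)
  empty <- build_profile(make_peaks("c1", integer(0), integer(0)), ex,
                         params)
  expect_true(all(empty$observed == 0L))
  expect_error(build_profile(make_peaks("c1", 1L, 2L),
                             make_exons(integer(0), integer(0)), params),
               "empty")
  # one peak at +25 lands in the innermost downstream bin
  one <- build_profile(make_peaks("c1", 1120L, 1131L), ex, params)
  hit <- one[one$observed > 0, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$side, "downstream")
  expect_identical(hit$bin_start, 0L)
  expect_identical(hit$bin_end, 50L)
})

test_that("binned counts equal brute-force pair enumeration", {
  params <- rna_map_params(window = 300L, bin_width = 50L,
                           n_bootstrap = 10L)
  withr::with_seed(31, {
    ex <- make_exons(seq(2000L, by = 3000L, length.out = 15),
                     seq(2000L, by = 3000L, length.out = 15) + 120L,
                     strand = sample(c("+", "-"), 15, TRUE))
    pos <- sample.int(50000L, 200)
    pk <- make_peaks("c1", pos, pos + 11L,
                     strand = sample(c("+", "-"), 200, TRUE))
  })
  prof <- build_profile(pk, ex, params)
  # O(peaks x exons) oracle
  oracle <- integer(nrow(prof))
  for (i in seq_len(nrow(pk))) {
    m <- floor((pk$start[i] + pk$end[i]) / 2)
    for (j in seq_len(nrow(ex))) {
      if (pk$strand[i] != ex$strand[j]) next
      s <- ex$start[j]; e <- ex$end[j]; minus <- ex$strand[j] == "-"
      if (m >= s && m < e) {
        side <- "exon"; d <- 0L
      } else if (m >= e) {
        side <- if (minus) "upstream" else "downstream"; d <- m - e + 1L
      } else {
        side <- if (minus) "downstream" else "upstream"; d <- s - m
      }
      if (side != "exon" && d > params$window) next
      nb <- params$window %/% params$bin_width
      bin <- if (side == "exon") nb + 1L else {
        ws <- (d - 1L) %/% params$bin_width
        if (side == "upstream") nb - ws else nb + 2L + ws
      }
      oracle[bin] <- oracle[bin] + 1L
    }
  }
  expect_identical(prof$observed, oracle)
  expect_identical(sum(prof$observed), sum(oracle))
})

test_that("bootstrap null: floor, identity hook, and analytic expectation", {
  params <- rna_map_params(window = 300L, bin_width = 50L,
                           n_bootstrap = 50L, seed = 5L)
  ins <- make_exons(seq(2000L, by = 3000L, length.out = 20),
                    seq(2000L, by = 3000L, length.out = 20) + 100L)
  # no peaks anywhere -> lambda at the floor in every bin
  lam0 <- bootstrap_null_profile(make_peaks("c1", integer(0), integer(0)),
                                 ins, n_sample = 10L, params)
  expect_true(all(lam0 == params$lambda_floor))
  expect_error(bootstrap_null_profile(make_peaks("c1", 1L, 2L), ins[1:3, ],
                                      5L, params), ">= 10")
  # identity hook reproduces the plain insensitive profile
  withr::with_seed(32, {
    pos <- sample.int(60000L, 400)
    pk <- make_peaks("c1", pos, pos + 11L)
  })
  lam_id <- bootstrap_null_profile(pk, ins, n_sample = 20L, params,
                                   identity = TRUE)
  prof_ins <- build_profile(pk, ins, params)
  expect_equal(unname(lam_id), pmax(prof_ins$observed,
                                    params$lambda_floor))
  # uniform planted rate: lambda ~ n_sample * per-exon bin rate
  lam <- bootstrap_null_profile(pk, ins, n_sample = 40L, params)
  flank <- lam[prof_ins$side != "exon"]
  expected <- 40 * sum(prof_ins$observed[prof_ins$side != "exon"]) /
    (20 * sum(prof_ins$side != "exon"))
  expect_lt(abs(mean(flank) - expected) / expected, 0.25)
  # deterministic under a fixed seed
  lam2 <- bootstrap_null_profile(pk, ins, n_sample = 40L, params)
  expect_identical(lam, lam2)
})

test_that("Poisson tails match direct summation and BH is monotone", {
  pe <- poisson_enrichment(c(0L, 5L), c(2, 1))
  expect_equal(pe$p[1], 1)
  # closed-form oracle: 1 - sum_{x<=4} e^{-1}/x!
  p_direct <- 1 - sum(exp(-1) / factorial(0:4))
  expect_equal(pe$p[2], p_direct, tolerance = 1e-12)
  expect_error(poisson_enrichment(c(-1L), c(1)), "negative")

  withr::with_seed(33, {
    obs <- rpois(40, 3)
    lam <- runif(40, 0.5, 6)
  })
  pe2 <- poisson_enrichment(obs, lam)
  ord <- order(pe2$p)
  expect_true(all(diff(pe2$fdr[ord]) >= -1e-12))
  expect_true(all(pe2$fdr >= pe2$p - 1e-12))
})

test_that("rna map output is deterministic and conserves counts", {
  sim <- simulate_genome_annotation(fast_sim_config(seed = 16))
  tables <- simulate_splicing_counts(sim$truth)
  pk <- filter_peaks_stringent(
    simulate_peaks(sim$truth, genes = sim$annotation$genes)$peaks)
  se <- tables$SE
  sig <- filter_significant(se, dpsi_min = 0.05)
  ins <- select_insensitive(se)
  exo <- function(e) make_exons(e$exon1_start, e$exon1_end,
                                contig = e$contig, strand = e$strand)
  params <- rna_map_params(window = 300L, n_bootstrap = 100L, seed = 2L)
  m1 <- build_rna_map(pk, exo(sig), exo(ins), params)
  m2 <- build_rna_map(pk, exo(sig), exo(ins), params)
  expect_identical(tibble::as_tibble(m1), tibble::as_tibble(m2))
  pairs <- peak_metacoordinate(pk, exo(sig), params$window)
  in_window <- sum(pairs$side == "exon" | pairs$dist <= params$window)
  expect_identical(sum(m1$observed), in_window)
  gl <- glance(m1)
  expect_identical(gl$n_exons, nrow(sig))
  expect_identical(gl$total_observed, sum(m1$observed))
})

test_that("flank tests recover a planted one-sided signal", {
  # directly constructed geometry: plant peaks only downstream of
  # included exons at a 5x rate over a uniform background
  base <- seq(5000L, by = 4000L, length.out = 140)
  withr::with_seed(34, {
    cls <- sample(rep(c("included", "skipped", "insensitive"),
                      c(20, 20, 100)))
    ex <- make_exons(base, base + 120L)
    peaks <- list()
    for (i in seq_along(base)) {
      # uniform background around every exon
      n_bg <- rpois(1, 0.5)
      if (n_bg > 0) {
        off <- sample(c(-1, 1), n_bg, TRUE) * sample.int(600L, n_bg)
        mid <- ifelse(off > 0, ex$end[i] + off, ex$start[i] + off)
        peaks[[length(peaks) + 1L]] <- tibble::tibble(mid = mid)
      }
      if (cls[i] == "included") {
        n_sig <- rpois(1, 2.5)
        if (n_sig > 0) {
          peaks[[length(peaks) + 1L]] <-
            tibble::tibble(mid = ex$end[i] + sample.int(150L, n_sig,
                                                        replace = TRUE))
        }
      }
    }
    mids <- dplyr::bind_rows(peaks)$mid
  })
  pk <- make_peaks("c1", as.integer(mids - 5L), as.integer(mids + 6L))
  params <- rna_map_params(window = 300L, n_bootstrap = 200L, seed = 9L)
  ft <- flank_enrichment_test(pk, ex[cls == "included", ],
                              ex[cls == "skipped", ],
                              ex[cls == "insensitive", ], params)
  expect_identical(nrow(ft), 4L)
  di <- ft[ft$side == "downstream" & ft$exon_class == "included", ]
  expect_lte(di$fdr, 0.05)
  others <- ft[!(ft$side == "downstream" & ft$exon_class == "included"), ]
  expect_true(all(others$fdr > 0.05))
  # no peaks -> all four p = 1
  ft0 <- flank_enrichment_test(make_peaks("c1", integer(0), integer(0)),
                               ex[cls == "included", ],
                               ex[cls == "skipped", ],
                               ex[cls == "insensitive", ], params)
  expect_true(all(ft0$p == 1))
  # empty class skipped with a warning (one per affected side)
  w <- testthat::capture_warnings(
    flank_enrichment_test(pk, ex[cls == "included", ],
                          ex[0, ], ex[cls == "insensitive", ], params))
  expect_true(any(grepl("skipped", w)))
})

test_that("MXE maps assign classes by dPSI sign with complementary exons", {
  ev <- make_events(4, event_type = "MXE", dpsi = c(0.3, 0.3, -0.3, -0.3),
                    fdr = rep(0.01, 4))
  ev$exon2_start <- ev$exon1_end + 200L
  ev$exon2_end <- ev$exon2_start + 100L
  ev$downstream_start <- ev$exon2_end + 200L
  ev$downstream_end <- ev$downstream_start + 100L
  ev$direction <- ifelse(ev$dpsi > 0, "included", "skipped")
  ins <- make_exons(seq(50000L, by = 2000L, length.out = 12),
                    seq(50000L, by = 2000L, length.out = 12) + 100L)
  params <- rna_map_params(window = 300L, n_bootstrap = 20L, seed = 1L)
  maps <- build_mxe_maps(make_peaks("c1", 100L, 111L), ev, ins, params)
  expect_setequal(names(maps), c("exon1_included", "exon1_skipped",
                                 "exon2_included", "exon2_skipped"))
  # exon1 included set = events with dpsi > 0; exon2 included = dpsi < 0
  expect_identical(attr(maps$exon1_included, "n_exons"), 2L)
  expect_identical(attr(maps$exon2_included, "n_exons"), 2L)
  w <- testthat::capture_warnings(
    build_mxe_maps(make_peaks("c1", 100L, 111L),
                   ev[ev$dpsi > 0, ], ins, params))
  expect_true(any(grepl("no MXE events", w)))
})

test_that("map parameters are validated", {
  expect_error(rna_map_params(window = 325L), "divisible")
  expect_error(rna_map_params(n_bootstrap = 0L), ">= 1")
  expect_error(rna_map_params(window = 100L, flank_test_width = 150L),
               "flank_test_width")
  p <- rna_map_params(n_bootstrap = 500L)
  expect_equal(p$lambda_floor, 1 / 500)
})
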