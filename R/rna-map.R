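#' Parameters for position-dependent RNA splicing maps
#'
#' @param window Half-window in nt on each side of the exon (2000 for the
#'   wide map, 300 for the fine map). Must be divisible by `bin_width`.
#' @param bin_width Bin width in nt (default 50).
#' @param n_bootstrap Number of bootstrap resamples B (default 1000).
#' @param seed Integer seed fixing all bootstrap randomness.
#' @param flank_test_width Width in nt of the innermost flank region used
#'   by the four side-by-class tests (default 150).
#' @param lambda_floor Floor on the per-bin null rate so Poisson tails stay
#'   defined when the null is empty; default `1/n_bootstrap`.
#' @return An `rna_map_params` list.
#' @export
rna_map_params <- function(window = 2000L, bin_width = 50L,
                           n_bootstrap = 1000L, seed = 1L,
                           flank_test_width = 150L, lambda_floor = NULL) {
  window <- as.integer(window); bin_width <- as.integer(bin_width)
  n_bootstrap <- as.integer(n_bootstrap)
  if (window %% bin_width != 0L) {
    stop("window must be divisible by bin_width", call. = FALSE)
  }
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1", call. = FALSE)
  if (flank_test_width > window) {
    stop("flank_test_width must be <= window", call. = FALSE)
  }
  if (is.null(lambda_floor)) lambda_floor <- 1 / n_bootstrap
  structure(list(window = window, bin_width = bin_width,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed),
                 flank_test_width = as.integer(flank_test_width),
                 lambda_floor = lambda_floor),
            class = "rna_map_params")
}

#' Metacoordinates of peaks relative to exons
#'
#' Computes, for every same-contig same-strand (peak, exon) pair within
#' `window` nt, the peak midpoint's position on the meta-exon axis:
#' `side = "exon"` (midpoint inside the exon, `pos = 0`),
#' `"downstream"` (positive offsets past the exon 3' boundary in transcript
#' orientation) or `"upstream"` (negative offsets before the 5' boundary).
#' Orientation flips on the minus strand: a midpoint genomically after a
#' minus-strand exon is upstream of it.
#'
#' @param peaks Peak tibble (`contig`, `start`, `end`, `strand`).
#' @param exons Exon tibble (`contig`, `start`, `end`, `strand`).
#' @param window Maximum distance in nt from the exon boundary.
#' @return Tibble: `peak_idx`, `exon_idx` (row indices into the inputs),
#'   `side`, `pos` (signed nt offset), `dist` (non-negative genomic
#'   distance used for binning).
#' @export
peak_metacoordinate <- function(peaks, exons, window = 2000L) {
  pk <- tibble::as_tibble(peaks); ex <- tibble::as_tibble(exons)
  if (nrow(pk) == 0L || nrow(ex) == 0L) {
    return(tibble::tibble(peak_idx = integer(), exon_idx = integer(),
                          side = character(), pos = integer(),
                          dist = integer()))
  }
  mid <- peak_midpoint(pk)
  q <- GenomicRanges::GRanges(pk$contig,
                              IRanges::IRanges(mid + 1L, width = 1L),
                              strand = pk$strand)
  s <- GenomicRanges::GRanges(
    ex$contig,
    IRanges::IRanges(pmax(ex$start - window, 0L) + 1L, ex$end + window),
    strand = ex$strand
  )
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
  pi <- S4Vectors::queryHits(hits); ei <- S4Vectors::subjectHits(hits)
  m <- mid[pi]
  es <- ex$start[ei]; ee <- ex$end[ei]; st <- ex$strand[ei]
  inside <- m >= es & m < ee
  after <- m >= ee                       # genomically past the exon
  side <- ifelse(inside, "exon",
                 ifelse(after == (st == "+"), "downstream", "upstream"))
  # signed display offset: boundary-relative midpoint position
  pos <- ifelse(inside, 0L,
                ifelse(after, ifelse(st == "+", m - ee, -(m - ee)),
                       ifelse(st == "+", m - es, es - m)))
  # 1-based transcript-oriented distance (innermost flank base = 1),
  # used for window membership and binning on both strands alike
  dist <- ifelse(inside, 0L, ifelse(after, m - ee + 1L, es - m))
  keep <- inside | dist <= window
  tibble::tibble(peak_idx = pi[keep], exon_idx = ei[keep],
                 side = side[keep], pos = as.integer(pos[keep]),
                 dist = as.integer(dist[keep]))
}

meta_axis <- function(params) {
  nb <- params$window %/% params$bin_width
  bw <- params$bin_width
  tibble::tibble(
    bin = seq_len(2L * nb + 1L),
    side = c(rep("upstream", nb), "exon", rep("downstream", nb)),
    bin_start = c(-(nb:1) * bw, 0L, (0:(nb - 1L)) * bw),
    bin_end = c(-((nb - 1L):0) * bw, 0L, (1:nb) * bw)
  )
}

# per-exon bin-count matrix (n_exons x n_bins); bin order = meta_axis order
exon_bin_matrix <- function(peaks, exons, params) {
  nb <- params$window %/% params$bin_width
  n_bins <- 2L * nb + 1L
  pr <- peak_metacoordinate(peaks, exons, params$window)
  m <- matrix(0L, nrow(tibble::as_tibble(exons)), n_bins)
  if (nrow(pr) == 0L) return(m)
  within_side <- (pr$dist - 1L) %/% params$bin_width
  bin <- ifelse(pr$side == "exon", nb + 1L,
                ifelse(pr$side == "upstream", nb - within_side,
                       nb + 2L + within_side))
  idx <- (bin - 1L) * nrow(m) + pr$exon_idx
  m <- m + matrix(tabulate(idx, nbins = length(m)), nrow(m), n_bins)
  m
}

#' Observed meta-exon binding profile
#'
#' Bins peak midpoints on the meta-exon axis over an exon set; each
#' (peak, exon) pair within the window contributes exactly once, to one
#' bin. The exon body is collapsed to a single dedicated `"exon"` bin.
#'
#' @param peaks Peak tibble.
#' @param exon_set Non-empty exon tibble.
#' @param params An [rna_map_params()].
#' @return Tibble: `bin`, `side`, `bin_start`, `bin_end`, `observed`, plus
#'   `per_exon` (observed divided by the number of exons, for plotting);
#'   attribute `n_exons`.
#' @export
build_profile <- function(peaks, exon_set, params = rna_map_params()) {
  ex <- tibble::as_tibble(exon_set)
  if (nrow(ex) == 0L) stop("empty exon set", call. = FALSE)
  m <- exon_bin_matrix(peaks, ex, params)
  ax <- meta_axis(params)
  ax$observed <- as.integer(colSums(m))
  ax$per_exon <- ax$observed / nrow(ex)
  attr(ax, "n_exons") <- nrow(ex)
  ax
}

#' Bootstrap null profile from insensitive exons
#'
#' Estimates the per-bin expected peak count under no position-dependent
#' regulation: B times, draw `n_sample` insensitive exons with replacement
#' and bin the peaks around them; the null rate is the per-bin mean count
#' over draws, floored at `lambda_floor`. Deterministic for a fixed
#' `params$seed`.
#'
#' @param peaks Peak tibble.
#' @param insensitive_exons Exon tibble of splicing-insensitive exons
#'   (>= 10 rows).
#' @param n_sample Size of the sensitive set being tested (each resample
#'   draws this many exons).
#' @param params An [rna_map_params()].
#' @param identity If `TRUE`, skip resampling and use every insensitive
#'   exon exactly once (degenerate single-draw null, for testing).
#' @return Numeric vector `lambda`, one value per meta-axis bin.
#' @export
bootstrap_null_profile <- function(peaks, insensitive_exons, n_sample,
                                   params = rna_map_params(),
                                   identity = FALSE) {
  ex <- tibble::as_tibble(insensitive_exons)
  if (nrow(ex) < 10L && !identity) {
    stop("need >= 10 insensitive exons for the bootstrap null",
         call. = FALSE)
  }
  m <- exon_bin_matrix(peaks, ex, params)
  if (identity) {
    lam <- colSums(m)
  } else {
    B <- params$n_bootstrap
    tot <- numeric(ncol(m))
    withr::with_seed(params$seed, {
      for (b in seq_len(B)) {
        idx <- sample.int(nrow(ex), n_sample, replace = TRUE)
        tot <- tot + colSums(m[idx, , drop = FALSE])
      }
    })
    lam <- tot / B
  }
  pmax(lam, params$lambda_floor)
}

#' Poisson enrichment of an observed profile over a null
#'
#' Per bin, the one-sided (enrichment) tail probability
#' `P(X >= observed)` for `X ~ Poisson(lambda)`, Benjamini-Hochberg
#' adjusted across the bins of the profile, with the conventional
#' significance stars.
#'
#' @param observed Integer vector of observed per-bin counts.
#' @param lambda Numeric vector of null rates, same length.
#' @return Tibble: `observed`, `lambda`, `enrichment`, `p`, `fdr`, `stars`.
#' @export
poisson_enrichment <- function(observed, lambda) {
  stopifnot(length(observed) == length(lambda))
  if (any(observed < 0)) stop("negative observed count", call. = FALSE)
  p <- stats::ppois(observed - 1, lambda, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    observed = as.integer(observed), lambda = as.numeric(lambda),
    enrichment = observed / lambda, p = p, fdr = fdr,
    stars = cut(fdr, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                labels = c("****", "***", "**", "*", "ns"))
  )
}

#' Build a full RNA splicing map for one exon class
#'
#' Combines [build_profile()] on the sensitive exon set,
#' [bootstrap_null_profile()] on the insensitive set (resample size equal
#' to the sensitive set size), and [poisson_enrichment()] per bin.
#'
#' @param peaks Peak tibble.
#' @param sensitive_exons Exon tibble of the class being mapped (e.g.
#'   included cassette exons).
#' @param insensitive_exons Exon tibble of unchanged exons (the null).
#' @param params An [rna_map_params()].
#' @param label Optional class label stored on the object.
#' @return A `meta_exon_profile` tibble: meta-axis columns plus `observed`,
#'   `per_exon`, `lambda`, `enrichment`, `p`, `fdr`, `stars`; attributes
#'   `n_exons`, `n_insensitive`, `params`, `label`.
#' @export
build_rna_map <- function(peaks, sensitive_exons, insensitive_exons,
                          params = rna_map_params(), label = NULL) {
  prof <- build_profile(peaks, sensitive_exons, params)
  lam <- bootstrap_null_profile(peaks, insensitive_exons,
                                n_sample = attr(prof, "n_exons"),
                                params = params)
  enr <- poisson_enrichment(prof$observed, lam)
  out <- dplyr::bind_cols(
    prof, dplyr::select(enr, "lambda", "enrichment", "p", "fdr", "stars")
  )
  class(out) <- c("meta_exon_profile", class(out))
  attr(out, "n_exons") <- attr(prof, "n_exons")
  attr(out, "n_insensitive") <- nrow(tibble::as_tibble(insensitive_exons))
  attr(out, "params") <- params
  attr(out, "label") <- label
  out
}

# per-exon count of peak midpoints in the innermost `width` nt of one flank
flank_region_counts <- function(peaks, exons, side, width) {
  ex <- tibble::as_tibble(exons)
  pr <- peak_metacoordinate(peaks, ex, window = width)
  pr <- pr[pr$side == side & pr$dist >= 1L & pr$dist <= width, ,
           drop = FALSE]
  cnt <- integer(nrow(ex))
  if (nrow(pr) > 0L) {
    t <- table(factor(pr$exon_idx, levels = seq_len(nrow(ex))))
    cnt <- as.integer(t)
  }
  cnt
}

#' Flank enrichment tests: 150 nt immediately up/downstream
#'
#' Tests peak enrichment in the innermost `flank_test_width` nt of each
#' intronic flank for each regulation class, against the bootstrap null
#' from insensitive exons, treating the region as a single bin. The four
#' (side x class) p-values are BH-adjusted together. Classes with no exons
#' are skipped with a warning.
#'
#' @param peaks Peak tibble.
#' @param included_exons,skipped_exons Exon tibbles of the two regulation
#'   classes.
#' @param insensitive_exons Exon tibble for the null.
#' @param params An [rna_map_params()].
#' @return A `flank_test` tibble: `side`, `exon_class`, `n_exons`,
#'   `observed`, `lambda`, `enrichment`, `p`, `fdr`.
#' @export
flank_enrichment_test <- function(peaks, included_exons, skipped_exons,
                                  insensitive_exons,
                                  params = rna_map_params()) {
  w <- params$flank_test_width
  ins <- tibble::as_tibble(insensitive_exons)
  if (nrow(ins) < 10L) {
    stop("need >= 10 insensitive exons", call. = FALSE)
  }
  classes <- list(included = tibble::as_tibble(included_exons),
                  skipped = tibble::as_tibble(skipped_exons))
  grid <- expand.grid(side = c("upstream", "downstream"),
                      exon_class = c("included", "skipped"),
                      stringsAsFactors = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    side <- grid$side[i]; cls <- grid$exon_class[i]
    ex <- classes[[cls]]
    if (nrow(ex) == 0L) {
      warning("no '", cls, "' exons: ", side, " test skipped",
              call. = FALSE)
      return(NULL)
    }
    obs <- sum(flank_region_counts(peaks, ex, side, w))
    null_cnt <- flank_region_counts(peaks, ins, side, w)
    B <- params$n_bootstrap
    lam <- withr::with_seed(params$seed + i, {
      mean(vapply(seq_len(B), function(b) {
        sum(null_cnt[sample.int(nrow(ins), nrow(ex), replace = TRUE)])
      }, numeric(1)))
    })
    lam <- max(lam, params$lambda_floor)
    tibble::tibble(side = side, exon_class = cls, n_exons = nrow(ex),
                   observed = obs, lambda = lam, enrichment = obs / lam,
                   p = stats::ppois(obs - 1, lam, lower.tail = FALSE))
  })
  rows$fdr <- stats::p.adjust(rows$p, method = "BH")
  class(rows) <- c("flank_test", class(rows))
  attr(rows, "params") <- params
  rows
}

#' RNA maps for mutually exclusive exon (MXE) events
#'
#' Builds four profiles — {1st exon, 2nd exon} x {included, skipped} — from
#' significant MXE events, each against the bootstrap null from insensitive
#' exons. The 1st-exon class comes from the ΔPSI sign (positive means the
#' 1st exon is included under the control condition); the 2nd exon takes
#' the complementary class.
#'
#' @param peaks Peak tibble.
#' @param mxe_events Significant MXE event tibble (with `direction`).
#' @param insensitive_exons Exon tibble for the null.
#' @param params An [rna_map_params()].
#' @return Named list of `meta_exon_profile` objects
#'   (`exon1_included`, `exon1_skipped`, `exon2_included`,
#'   `exon2_skipped`); entries are `NULL` (with a warning) when a class is
#'   empty.
#' @export
build_mxe_maps <- function(peaks, mxe_events, insensitive_exons,
                           params = rna_map_params()) {
  ev <- tibble::as_tibble(mxe_events)
  ev <- ev[ev$event_type == "MXE", , drop = FALSE]
  if (!"direction" %in% names(ev)) {
    ev$direction <- ifelse(ev$dpsi > 0, "included", "skipped")
  }
  pick <- function(which_exon, cls) {
    cls1 <- if (which_exon == 1L) cls else
      ifelse(cls == "included", "skipped", "included")
    sub <- ev[ev$direction == cls1, , drop = FALSE]
    s <- if (which_exon == 1L) sub$exon1_start else sub$exon2_start
    e <- if (which_exon == 1L) sub$exon1_end else sub$exon2_end
    tibble::tibble(contig = sub$contig, start = s, end = e,
                   strand = sub$strand)
  }
  out <- list()
  for (we in 1:2) {
    for (cls in c("included", "skipped")) {
      nm <- paste0("exon", we, "_", cls)
      ex <- pick(we, cls)
      if (nrow(ex) == 0L) {
        warning("no MXE events for ", nm, call. = FALSE)
        out[[nm]] <- NULL
      } else {
        out[[nm]] <- build_rna_map(peaks, ex, insensitive_exons, params,
                                   label = nm)
      }
    }
  }
  out
}
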