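#' Configuration for the synthetic splicing/CLIP data generator
#'
#' Defines the simulated study conditions: multi-exon genes on both
#' strands, a subset of sensitive cassette (SE) and mutually exclusive
#' (MXE) exons with ΔPSI effects, GCATG motifs planted in the designated
#' 150-nt intronic flank (downstream of included exons, upstream of
#' skipped exons), CLIP peaks of realistic width centered near motifs, and
#' replicate junction counts yielding rMATS-dialect tables. A single seed
#' fixes all downstream randomness.
#'
#' @param n_genes Number of genes (default 200).
#' @param exons_per_gene Integer range, exons per gene (default 5–8; at
#'   least 4 so internal exon pairs exist).
#' @param exon_length,intron_length Length ranges in nt.
#' @param intergenic_gap Gap between consecutive genes in nt.
#' @param frac_sensitive_se Fraction of cassette exons that are splicing
#'   sensitive (default 0.25).
#' @param frac_mxe Fraction of genes carrying an MXE pair instead of a
#'   cassette exon (default 0.10).
#' @param frac_sensitive_mxe Fraction of MXE pairs that are sensitive.
#' @param dpsi_magnitude |ΔPSI| planted on sensitive events (default 0.4);
#'   sign follows the included/skipped class.
#' @param motif Consensus element written into designated flanks
#'   (default `"GCATG"`, the RBFOX element in DNA alphabet).
#' @param motif_flank_rate Probability that a designated 150-nt flank of a
#'   sensitive exon receives a planted motif (default 0.5).
#' @param motif_bg_rate Expected planted motifs per nt outside designated
#'   flanks (default 0; chance occurrences still arise from background
#'   sequence at rate 4^-5 per nt).
#' @param flank_width Designated flank width in nt (default 150).
#' @param plant_classes Regulation classes whose designated flanks receive
#'   motifs (default both; set to `"included"` to plant signal only
#'   downstream of included exons, e.g. for specificity checks).
#' @param peak_width_mean,peak_width_sd,peak_width_min Peak width
#'   distribution, Normal(91, 15) truncated at 30 nt.
#' @param peak_detection Probability a planted motif yields a peak
#'   (default 0.8).
#' @param bg_peak_rate Expected background peaks per gene (default 3,
#'   i.e. about 0.5 background peaks per exon at 5-8 exons per gene).
#' @param weak_peak_frac Fraction of background peaks drawn to fail the
#'   stringent
#'   fold-enrichment/p filter (default 0.2).
#' @param replicates Replicates per condition (default 4).
#' @param coverage Junction reads per event per replicate (default 100).
#' @param psi_noise_sd Replicate-to-replicate PSI noise SD (default 0.01).
#' @param map_window Fine-map half-window the intron lengths must
#'   accommodate (validation: min intron >= 2 * map_window).
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L, exons_per_gene = c(5L, 8L),
                       exon_length = c(90L, 250L),
                       intron_length = c(700L, 1500L),
                       intergenic_gap = 2000L,
                       frac_sensitive_se = 0.25, frac_mxe = 0.10,
                       frac_sensitive_mxe = 0.25, dpsi_magnitude = 0.4,
                       motif = "GCATG", motif_flank_rate = 0.5,
                       motif_bg_rate = 0, flank_width = 150L,
                       plant_classes = c("included", "skipped"),
                       peak_width_mean = 91, peak_width_sd = 15,
                       peak_width_min = 30L, peak_detection = 0.8,
                       bg_peak_rate = 3, weak_peak_frac = 0.2,
                       replicates = 4L, coverage = 100L,
                       psi_noise_sd = 0.01, map_window = 300L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_gap = as.integer(intergenic_gap),
              frac_sensitive_se = frac_sensitive_se, frac_mxe = frac_mxe,
              frac_sensitive_mxe = frac_sensitive_mxe,
              dpsi_magnitude = dpsi_magnitude, motif = toupper(motif),
              motif_flank_rate = motif_flank_rate,
              motif_bg_rate = motif_bg_rate,
              flank_width = as.integer(flank_width),
              plant_classes = match.arg(plant_classes,
                                        c("included", "skipped"),
                                        several.ok = TRUE),
              peak_width_mean = peak_width_mean,
              peak_width_sd = peak_width_sd,
              peak_width_min = as.integer(peak_width_min),
              peak_detection = peak_detection,
              bg_peak_rate = bg_peak_rate,
              weak_peak_frac = weak_peak_frac,
              replicates = as.integer(replicates),
              coverage = as.integer(coverage),
              psi_noise_sd = psi_noise_sd,
              map_window = as.integer(map_window),
              seed = as.integer(seed))
  rates <- c(cfg$frac_sensitive_se, cfg$frac_mxe, cfg$frac_sensitive_mxe,
             cfg$motif_flank_rate, cfg$motif_bg_rate, cfg$peak_detection,
             cfg$weak_peak_frac)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$coverage < 1L) stop("coverage must be >= 1", call. = FALSE)
  if (cfg$exons_per_gene[1] < 4L) {
    stop("need at least 4 exons per gene", call. = FALSE)
  }
  if (cfg$intron_length[1] < 2L * cfg$map_window) {
    stop("intron range too short for the map window: need min intron >= ",
         2L * cfg$map_window, " nt", call. = FALSE)
  }
  if (cfg$intron_length[1] < cfg$flank_width ||
      abs(cfg$dpsi_magnitude) > 1) {
    stop("invalid intron range or dpsi magnitude", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

resample1 <- function(x) x[sample.int(length(x), 1L)]

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# genomic interval of the designated flank, mirroring
# extract_flank_sequence(): after-the-exon <=> (down on +) or (up on -)
flank_interval <- function(start, end, strand, side, width) {
  after <- (strand == "+") == (side == "downstream")
  list(start = ifelse(after, end, start - width),
       end = ifelse(after, end + width, start))
}

#' Simulate a genome, annotation, and splicing ground truth
#'
#' Generates i.i.d. background sequence on one contig, lays out multi-exon
#' genes on both strands, designates one internal cassette exon (or an
#' adjacent MXE pair) per gene, assigns the sensitive subset with
#' included/skipped classes and planted ΔPSI, and writes the consensus
#' motif into the designated 150-nt flank of sensitive exons (downstream
#' of included, upstream of skipped; for MXE, relative to the 1st exon in
#' transcript orientation) at the configured rate.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (`genome_seq`), `annotation`
#'   (`genome_annotation`), `truth` (list with `events` and `motifs`
#'   tibbles plus the config).
#' @export
simulate_genome_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_genome_annotation_impl(config))
}

simulate_genome_annotation_impl <- function(cfg) {
  contig <- "chr1"
  cursor <- cfg$intergenic_gap
  exon_rows <- list(); gene_rows <- list(); event_rows <- list()
  n_mxe <- round(cfg$frac_mxe * cfg$n_genes)
  is_mxe <- seq_len(cfg$n_genes) %in%
    sample.int(cfg$n_genes, n_mxe)
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", i)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
    ex_len <- sample(seq(cfg$exon_length[1], cfg$exon_length[2]), n_ex,
                     replace = TRUE)
    in_len <- sample(seq(cfg$intron_length[1], cfg$intron_length[2]),
                     n_ex - 1L, replace = TRUE)
    starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    exon_rows[[i]] <- tibble::tibble(
      gene_id = gid, transcript_id = paste0(gid, ".t1"), contig = contig,
      start = starts, end = ends, strand = strand
    )
    gene_rows[[i]] <- tibble::tibble(gene_id = gid, contig = contig,
                                     start = starts[1], end = ends[n_ex],
                                     strand = strand, is_mxe = is_mxe[i])
    cursor <- ends[n_ex] + cfg$intergenic_gap
  }
  exons <- dplyr::bind_rows(exon_rows)
  genes <- dplyr::bind_rows(gene_rows)

  # designate events: genomic exon index -> transcript orientation
  for (i in seq_len(cfg$n_genes)) {
    ex <- exon_rows[[i]]
    n_ex <- nrow(ex)
    strand <- ex$strand[1]
    gid <- ex$gene_id[1]
    # transcript order = genomic order on '+', reversed on '-'
    tx_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    if (genes$is_mxe[i]) {
      # adjacent internal pair in transcript order
      j <- resample1(2:(n_ex - 2L))
      e1 <- tx_order[j]; e2 <- tx_order[j + 1L]
      up <- tx_order[j - 1L]; dn <- tx_order[j + 2L]
      event_rows[[i]] <- tibble::tibble(
        event_id = as.character(i), gene_id = gid, gene_symbol = gid,
        contig = ex$contig[1], strand = strand, event_type = "MXE",
        exon1_start = ex$start[e1], exon1_end = ex$end[e1],
        exon2_start = ex$start[e2], exon2_end = ex$end[e2],
        upstream_start = ex$start[up], upstream_end = ex$end[up],
        downstream_start = ex$start[dn], downstream_end = ex$end[dn]
      )
    } else {
      j <- resample1(2:(n_ex - 1L))
      cas <- tx_order[j]; up <- tx_order[j - 1L]; dn <- tx_order[j + 1L]
      event_rows[[i]] <- tibble::tibble(
        event_id = as.character(i), gene_id = gid, gene_symbol = gid,
        contig = ex$contig[1], strand = strand, event_type = "SE",
        exon1_start = ex$start[cas], exon1_end = ex$end[cas],
        exon2_start = NA_integer_, exon2_end = NA_integer_,
        upstream_start = ex$start[up], upstream_end = ex$end[up],
        downstream_start = ex$start[dn], downstream_end = ex$end[dn]
      )
    }
  }
  events <- dplyr::bind_rows(event_rows)

  # sensitivity and regulation class
  se <- events$event_type == "SE"
  sens <- logical(nrow(events))
  sens[se] <- stats::runif(sum(se)) < cfg$frac_sensitive_se
  sens[!se] <- stats::runif(sum(!se)) < cfg$frac_sensitive_mxe
  cls <- rep(NA_character_, nrow(events))
  cls[sens] <- sample(c("included", "skipped"), sum(sens), replace = TRUE)
  events$sensitive <- sens
  events$class <- cls
  events$true_dpsi <- ifelse(!sens, 0,
                             ifelse(cls == "included", cfg$dpsi_magnitude,
                                    -cfg$dpsi_magnitude))

  # background sequence, then write motifs into designated flanks
  genome_len <- max(genes$end) + cfg$intergenic_gap
  seq <- rand_dna(genome_len)
  motif <- cfg$motif
  mw <- nchar(motif)
  motif_rows <- list()
  for (r in which(sens)) {
    if (!(events$class[r] %in% cfg$plant_classes)) next
    if (stats::runif(1) >= cfg$motif_flank_rate) next
    side <- ifelse(events$class[r] == "included", "downstream", "upstream")
    fl <- flank_interval(events$exon1_start[r], events$exon1_end[r],
                         events$strand[r], side, cfg$flank_width)
    off <- sample.int(cfg$flank_width - mw + 1L, 1L) - 1L
    pos <- fl$start + off                       # 0-based genomic start
    ins <- if (events$strand[r] == "+") motif else revcomp(motif)
    substr(seq, pos + 1L, pos + mw) <- ins
    motif_rows[[length(motif_rows) + 1L]] <- tibble::tibble(
      contig = "chr1", start = as.integer(pos),
      strand = events$strand[r], motif = motif, context = "planted_flank",
      event_id = events$event_id[r]
    )
  }
  if (cfg$motif_bg_rate > 0) {
    n_bg <- stats::rpois(1L, cfg$motif_bg_rate * genome_len)
    if (n_bg > 0L) {
      pos <- sample.int(genome_len - mw, n_bg)
      std <- sample(c("+", "-"), n_bg, replace = TRUE)
      for (j in seq_len(n_bg)) {
        ins <- if (std[j] == "+") motif else revcomp(motif)
        substr(seq, pos[j] + 1L, pos[j] + mw) <- ins
      }
      motif_rows[[length(motif_rows) + 1L]] <- tibble::tibble(
        contig = "chr1", start = as.integer(pos), strand = std,
        motif = motif, context = "background", event_id = NA_character_
      )
    }
  }
  motifs <- if (length(motif_rows) > 0L) dplyr::bind_rows(motif_rows) else
    tibble::tibble(contig = character(), start = integer(),
                   strand = character(), motif = character(),
                   context = character(), event_id = character())

  genome <- structure(stats::setNames(seq, contig), class = "genome_seq")
  annotation <- build_annotation_object(exons, genes)
  truth <- list(events = events, motifs = motifs, config = cfg)
  list(genome = genome, annotation = annotation, truth = truth)
}

# assemble a genome_annotation from simulated exon/gene tables, including
# a CDS spanning mid-first-exon to mid-last-exon (so UTRs exist)
build_annotation_object <- function(exons, genes) {
  ex <- dplyr::arrange(exons, .data$contig, .data$transcript_id,
                       .data$start)
  ex <- dplyr::group_by(ex, .data$transcript_id)
  ex <- dplyr::mutate(ex, exon_rank = dplyr::row_number())
  ex <- dplyr::ungroup(ex)
  tr <- dplyr::summarise(
    dplyr::group_by(ex, .data$gene_id, .data$transcript_id, .data$contig,
                    .data$strand),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
  cds_span <- dplyr::summarise(
    dplyr::group_by(ex, .data$transcript_id),
    cds_start = as.integer(floor((min(.data$start) +
                                    min(.data$end[.data$exon_rank == 1])) /
                                   2)),
    cds_end = as.integer(ceiling(
      (max(.data$start[.data$exon_rank == max(.data$exon_rank)]) +
         max(.data$end)) / 2)),
    .groups = "drop"
  )
  cds <- dplyr::inner_join(ex, cds_span, by = "transcript_id")
  cds <- dplyr::filter(cds, .data$end > .data$cds_start,
                       .data$start < .data$cds_end)
  cds <- dplyr::transmute(cds, contig = .data$contig,
                          start = pmax(.data$start, .data$cds_start),
                          end = pmin(.data$end, .data$cds_end),
                          strand = .data$strand, gene_id = .data$gene_id,
                          transcript_id = .data$transcript_id)
  utr <- derive_utrs(ex, cds)
  structure(
    list(genes = dplyr::select(genes, "gene_id", "contig", "start", "end",
                               "strand"),
         transcripts = dplyr::select(tr, "gene_id", "transcript_id",
                                     "contig", "start", "end", "strand"),
         exons = dplyr::select(ex, "gene_id", "transcript_id", "contig",
                               "start", "end", "strand", "exon_rank"),
         introns = derive_introns(ex),
         cds = cds, utr5 = utr$utr5, utr3 = utr$utr3),
    class = "genome_annotation"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate replicate junction counts and rMATS-dialect tables
#'
#' Per event and replicate, PSI is drawn around class-specific means
#' (control and depleted condition differ by the planted ΔPSI, with small
#' replicate noise), inclusion junction counts are Binomial(coverage, PSI)
#' and skipping counts the complement. The per-event p-value is a pooled
#' two-proportion chi-square test between conditions — a generator device
#' standing in for the splicing engine's likelihood test, not a
#' reimplementation of it — and FDR is Benjamini-Hochberg within each
#' event-type table. `IncLevelDifference` is mean PSI(control) − mean
#' PSI(depleted), so positive values mark exons whose inclusion the RBP
#' promotes.
#'
#' @param truth Ground truth from [simulate_genome_annotation()].
#' @param config The same [sim_config()].
#' @return Named list of event tibbles in the [read_rmats_table()] layout:
#'   `SE` and (when present) `MXE`.
#' @export
simulate_splicing_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    ev <- truth$events
    n <- nrow(ev)
    reps <- config$replicates
    cov <- config$coverage
    psi0 <- stats::runif(n, 0.35, 0.65)
    mean1 <- clamp(psi0 + ev$true_dpsi / 2, 0.02, 0.98)
    mean2 <- clamp(psi0 - ev$true_dpsi / 2, 0.02, 0.98)
    draw <- function(mu) {
      psi <- clamp(stats::rnorm(reps, mu, config$psi_noise_sd), 0.01, 0.99)
      ijc <- stats::rbinom(reps, cov, psi)
      list(ijc = ijc, sjc = cov - ijc, psi = ijc / cov)
    }
    d1 <- lapply(mean1, draw)
    d2 <- lapply(mean2, draw)
    ev$ijc_1 <- lapply(d1, `[[`, "ijc")
    ev$sjc_1 <- lapply(d1, `[[`, "sjc")
    ev$ijc_2 <- lapply(d2, `[[`, "ijc")
    ev$sjc_2 <- lapply(d2, `[[`, "sjc")
    ev$inc_level_1 <- lapply(d1, `[[`, "psi")
    ev$inc_level_2 <- lapply(d2, `[[`, "psi")
    m1 <- vapply(ev$inc_level_1, mean, numeric(1))
    m2 <- vapply(ev$inc_level_2, mean, numeric(1))
    ev$dpsi <- round(m1 - m2, 3)
    ev$pvalue <- vapply(seq_len(n), function(i) {
      x <- c(sum(ev$ijc_1[[i]]), sum(ev$ijc_2[[i]]))
      tot <- c(sum(ev$ijc_1[[i]], ev$sjc_1[[i]]),
               sum(ev$ijc_2[[i]], ev$sjc_2[[i]]))
      suppressWarnings(stats::prop.test(x, tot)$p.value)
    }, numeric(1))
    out <- split(ev, ev$event_type)
    lapply(out, function(tb) {
      tb$fdr <- stats::p.adjust(tb$pvalue, method = "BH")
      tb$event_id <- as.character(seq_len(nrow(tb)))
      tb
    })
  })
}

#' Simulate a CLIP peak set from planted motifs
#'
#' Each planted motif yields a peak with the configured detection
#' probability: width Normal(mean 91, truncated), centered on the motif
#' with small jitter, on the motif strand. Background peaks are added per
#' gene at the configured Poisson rate, uniformly within the gene span on
#' the gene strand. Fold enrichment and p-value are drawn so that about
#' `weak_peak_frac` of peaks fail the stringent filter (fold enrichment
#' >= 2 and p < 1e-3), exercising the filter path.
#'
#' @param truth Ground truth from [simulate_genome_annotation()] (needs
#'   the annotation's gene table for background placement — pass the
#'   `sim` list or supply `genes`).
#' @param config The [sim_config()].
#' @param genes Gene tibble (`gene_id`, `contig`, `start`, `end`,
#'   `strand`); defaults to the gene spans recoverable from the truth
#'   events.
#' @return List: `peaks` (peak tibble in [read_peak_file()] layout) and
#'   `provenance` (tibble flagging each peak `motif` or `background`).
#' @export
simulate_peaks <- function(truth, config = truth$config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 2L, {
    mt <- truth$motifs
    mw <- nchar(config$motif)
    det <- stats::runif(nrow(mt)) < config$peak_detection
    mt <- mt[det, , drop = FALSE]
    center <- mt$start + mw %/% 2L +
      as.integer(round(stats::rnorm(nrow(mt), 0, 10)))
    rows <- tibble::tibble(contig = mt$contig, center = center,
                           strand = mt$strand, origin = "motif")
    if (!is.null(genes) && config$bg_peak_rate > 0) {
      nbg <- stats::rpois(nrow(genes), config$bg_peak_rate)
      gg <- genes[rep(seq_len(nrow(genes)), nbg), , drop = FALSE]
      if (nrow(gg) > 0L) {
        bgc <- gg$start + floor(stats::runif(nrow(gg)) *
                                  (gg$end - gg$start))
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          contig = gg$contig, center = as.integer(bgc),
          strand = gg$strand, origin = "background"
        ))
      }
    }
    n <- nrow(rows)
    w <- pmax(as.integer(round(stats::rnorm(n, config$peak_width_mean,
                                            config$peak_width_sd))),
              config$peak_width_min)
    start <- pmax(rows$center - w %/% 2L, 0L)
    # nonspecific background peaks are the weak ones; motif-driven binding
    # events carry high fold enrichment, as in input-normalized CLIP data
    weak <- rows$origin == "background" &
      stats::runif(n) < config$weak_peak_frac
    log2fc <- ifelse(weak,
                     stats::runif(n, 0.1, log2(1.9)),
                     stats::runif(n, 1.5, 4))
    pv <- ifelse(weak, stats::runif(n, 2e-3, 5e-2),
                 10^-stats::runif(n, 3.5, 8))
    peaks <- tibble::tibble(
      contig = rows$contig, start = as.integer(start),
      end = as.integer(start + w),
      peak_id = sprintf("pk%05d", seq_len(n)),
      strand = rows$strand, log2fc = log2fc,
      pvalue = pv, fold_enrichment = 2^log2fc, width = w
    )
    list(peaks = peaks,
         provenance = tibble::tibble(peak_id = peaks$peak_id,
                                     origin = rows$origin))
  })
}

#' Simulate a complete fixture bundle on disk
#'
#' Runs the three generators and writes `genome.fa`, `genes.gtf`,
#' `SE.MATS.JCEC.txt`, `MXE.MATS.JCEC.txt`, `peaks.bed`, `truth.json`, and
#' `config.yaml` into a directory. Every file is parseable by the package
#' readers, and the bundle is byte-identical across runs with the same
#' config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`genome`,
#'   `annotation`, `truth`, `events`, `peaks`, `provenance`) and `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome_annotation(config)
  tables <- simulate_splicing_counts(sim$truth, config)
  pks <- simulate_peaks(sim$truth, config, genes = sim$annotation$genes)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    se = file.path(dir, "SE.MATS.JCEC.txt"),
    mxe = file.path(dir, "MXE.MATS.JCEC.txt"),
    peaks = file.path(dir, "peaks.bed"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_fasta(sim$genome, paths$genome)
  write_gtf(sim$annotation, paths$gtf)
  write_rmats_table(tables$SE, paths$se)
  if (!is.null(tables$MXE)) write_rmats_table(tables$MXE, paths$mxe)
  write_peak_file(pks$peaks, paths$peaks)
  truth_json <- list(
    events = sim$truth$events,
    motifs = sim$truth$motifs,
    peak_provenance = pks$provenance
  )
  jsonlite::write_json(truth_json, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  yaml::write_yaml(unclass(config), paths$config)
  invisible(list(genome = sim$genome, annotation = sim$annotation,
                 truth = sim$truth, events = tables, peaks = pks$peaks,
                 provenance = pks$provenance, paths = paths))
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @param line_width Characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, line_width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- unclass(genome)[[nm]]
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts,
                         pmin(starts + line_width - 1L, nchar(s))), con)
  }
  invisible(path)
}
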