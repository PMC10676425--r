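#' Build a pipeline configuration
#'
#' Collects input paths and every analysis threshold, all defaulted to the
#' conventional values (FDR < 0.05, |ΔPSI| >= 0.01, 20-read support, fold
#' enrichment >= 2, peak p < 1e-3). The configuration is echoed into the
#' output directory for provenance.
#'
#' @param genome,gtf,se,peaks Required input paths (FASTA, GTF, rMATS SE
#'   table, BED6+2 peak file).
#' @param mxe Optional rMATS MXE table path.
#' @param out_dir Output directory.
#' @param fdr_max,dpsi_min,min_reads Event-filter thresholds.
#' @param min_fe,max_p Stringent peak-filter thresholds.
#' @param flank_length Intronic flank length in nt for the k-mer scan
#'   (default 200).
#' @param k_flank,k_peak K-mer sizes for flank and under-peak enrichment.
#' @param map An [rna_map_params()]; its seed is taken from `seed`.
#' @param peak_dialect A [peak_dialect()].
#' @param seed Master seed for all randomized stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome, gtf, se, peaks, mxe = NULL,
                            out_dir = tempfile("splicebind_out"),
                            fdr_max = 0.05, dpsi_min = 0.01,
                            min_reads = 20, min_fe = 2, max_p = 1e-3,
                            flank_length = 200L, k_flank = 5L,
                            k_peak = 6L,
                            map = rna_map_params(window = 300L),
                            peak_dialect = splicebind::peak_dialect(),
                            seed = 1L) {
  map$seed <- as.integer(seed)
  structure(list(genome = genome, gtf = gtf, se = se, mxe = mxe,
                 peaks = peaks, out_dir = out_dir, fdr_max = fdr_max,
                 dpsi_min = dpsi_min, min_reads = min_reads,
                 min_fe = min_fe, max_p = max_p,
                 flank_length = as.integer(flank_length),
                 k_flank = as.integer(k_flank),
                 k_peak = as.integer(k_peak), map = map,
                 peak_dialect = peak_dialect, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys fall back to the [pipeline_config()] defaults.
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments
#'   (`map` as a nested mapping of [rna_map_params()] fields).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$map)) y$map <- do.call(rna_map_params, y$map)
  if (!is.null(y$peak_dialect)) {
    y$peak_dialect <- do.call(peak_dialect, y$peak_dialect)
  }
  do.call(pipeline_config, y)
}

event_exon_table <- function(ev) {
  tibble::tibble(contig = ev$contig, start = ev$exon1_start,
                 end = ev$exon1_end, strand = ev$strand)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — event filtering, flank k-mer enrichment,
#' peak characterization, RNA splicing map with flank tests, and
#' direct-target calling — writing each stage's table under
#' `config$out_dir` plus a machine-readable `report.json`. Identical
#' config and seed reproduce the report byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list with the stage objects and
#'   `report` (the parsed report structure).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$genome, config$gtf, config$se, config$peaks,
              config$mxe)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input not found: ", p, call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- read_fasta(config$genome)
  annotation <- read_gtf(config$gtf)
  se <- read_rmats_table(config$se, "SE")
  mxe <- if (!is.null(config$mxe)) read_rmats_table(config$mxe, "MXE")
  peaks_all <- read_peak_file(config$peaks, config$peak_dialect)

  # --- stage: event filtering -------------------------------------------
  events_all <- if (is.null(mxe)) se else dplyr::bind_rows(se, mxe)
  sig <- filter_significant(events_all, fdr_max = config$fdr_max,
                            dpsi_min = config$dpsi_min,
                            min_reads = config$min_reads)
  ins <- select_insensitive(events_all, fdr_min = config$fdr_max,
                            min_reads = config$min_reads)
  sig_se <- sig[sig$event_type == "SE", , drop = FALSE]
  ins_se <- ins[ins$event_type == "SE", , drop = FALSE]

  # --- stage: flank k-mer enrichment ------------------------------------
  kmer <- lapply(c(downstream = "downstream", upstream = "upstream"),
                 function(side) {
    fg <- extract_flank_sequence(genome, event_exon_table(sig_se),
                                 side = side,
                                 length = config$flank_length)$flank_seq
    bg <- extract_flank_sequence(genome, event_exon_table(ins_se),
                                 side = side,
                                 length = config$flank_length)$flank_seq
    kmer_enrichment_test(fg, bg, k = config$k_flank)
  })

  # --- stage: peak characterization -------------------------------------
  peaks <- filter_peaks_stringent(peaks_all, min_fe = config$min_fe,
                                  max_p = config$max_p)
  peak_summary <- summarize_peak_set(peaks, annotation)
  bound <- assign_peaks_to_genes(peaks, annotation)

  # --- stage: RNA map + flank tests -------------------------------------
  inc_ex <- event_exon_table(sig_se[sig_se$direction == "included", ])
  skp_ex <- event_exon_table(sig_se[sig_se$direction == "skipped", ])
  ins_ex <- event_exon_table(ins_se)
  maps <- list(
    included = if (nrow(inc_ex) > 0L)
      build_rna_map(peaks, inc_ex, ins_ex, config$map, "included"),
    skipped = if (nrow(skp_ex) > 0L)
      build_rna_map(peaks, skp_ex, ins_ex, config$map, "skipped")
  )
  flank <- flank_enrichment_test(peaks, inc_ex, skp_ex, ins_ex,
                                 params = config$map)

  # --- stage: direct targets --------------------------------------------
  targets <- call_direct_targets(bound$bound_genes, sig)
  intron_counts <- peaks_by_flanking_intron(sig, peaks)

  # --- outputs ----------------------------------------------------------
  readr::write_tsv(kmer$downstream,
                   file.path(config$out_dir, "kmer_downstream.tsv"),
                   progress = FALSE)
  readr::write_tsv(kmer$upstream,
                   file.path(config$out_dir, "kmer_upstream.tsv"),
                   progress = FALSE)
  readr::write_tsv(flank, file.path(config$out_dir, "flank_tests.tsv"),
                   progress = FALSE)
  readr::write_tsv(intron_counts,
                   file.path(config$out_dir, "event_intron_peaks.tsv"),
                   progress = FALSE)
  for (nm in names(maps)) {
    if (!is.null(maps[[nm]])) {
      readr::write_tsv(tibble::as_tibble(maps[[nm]]),
                       file.path(config$out_dir,
                                 paste0("rna_map_", nm, ".tsv")),
                       progress = FALSE)
    }
  }
  write_peak_file(peaks, file.path(config$out_dir,
                                   "peaks_stringent.bed"))
  write_event_table(sig, file.path(config$out_dir,
                                   "events_significant.tsv"))
  cfg_echo <- unclass(config)
  cfg_echo$map <- unclass(cfg_echo$map)
  cfg_echo$peak_dialect <- unclass(cfg_echo$peak_dialect)
  yaml::write_yaml(cfg_echo, file.path(config$out_dir, "config.yaml"))

  stages <- list(
    events = list(n_input = nrow(events_all), n_significant = nrow(sig),
                  n_insensitive = nrow(ins),
                  n_included = nrow(inc_ex), n_skipped = nrow(skp_ex),
                  thresholds = list(fdr_max = config$fdr_max,
                                    dpsi_min = config$dpsi_min,
                                    min_reads = config$min_reads)),
    kmer = list(
      downstream_top10 = utils::head(kmer$downstream, 10L),
      upstream_top10 = utils::head(kmer$upstream, 10L)
    ),
    peaks = list(n_input = nrow(peaks_all), n_stringent = nrow(peaks),
                 n_bound_genes = peak_summary$n_genes,
                 widths = peak_summary$widths,
                 features = peak_summary$features,
                 thresholds = list(min_fe = config$min_fe,
                                   max_p = config$max_p)),
    rna_map = list(flank_tests = flank),
    targets = list(n_direct = length(targets$direct_targets),
                   n_events = targets$n_events,
                   events_by_type = targets$events_by_type)
  )
  report <- make_report(stages)
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")

  structure(list(config = config, significant = sig, insensitive = ins,
                 kmer = kmer, peaks = peaks, peak_summary = peak_summary,
                 bound = bound, maps = maps, flank = flank,
                 targets = targets, intron_counts = intron_counts,
                 report = report, report_path = report_path),
            class = "pipeline_result")
}

#' Aggregate stage outputs into the report structure
#'
#' Pure aggregation: counts are copied from the stage outputs, nothing is
#' recomputed. Absent stages yield `NULL` sections.
#'
#' @param stages Named list with any of `events`, `kmer`, `peaks`,
#'   `rna_map`, `targets`.
#' @return A list ready for [jsonlite::write_json()].
#' @export
make_report <- function(stages) {
  section <- function(nm) if (nm %in% names(stages)) stages[[nm]]
  list(tool = "splicebind",
       events = section("events"),
       kmer = section("kmer"),
       peaks = section("peaks"),
       rna_map = section("rna_map"),
       targets = section("targets"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat("  events: ", r$events$n_significant, " significant / ",
      r$events$n_input, " input (", r$events$n_insensitive,
      " insensitive)\n", sep = "")
  cat("  peaks: ", r$peaks$n_stringent, " stringent / ", r$peaks$n_input,
      " input in ", r$peaks$n_bound_genes, " genes\n", sep = "")
  cat("  top downstream k-mer: ",
      r$kmer$downstream_top10$kmer[1], "\n", sep = "")
  cat("  direct targets: ", r$targets$n_direct, " genes / ",
      r$targets$n_events, " events\n", sep = "")
  invisible(x)
}
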