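#' Run the full QTL-seq pipeline
#'
#' Simulate (or load) pooled allele depths, run the SNP-index scan, and —
#' when a reference genome is available — design InDel markers in the top
#' candidate interval and narrow it by substitution mapping over a
#' simulated recombinant panel. Optionally annotates variants in the top
#' interval when gene models are supplied. All parameters are validated
#' before any output is written, every stage logs one structured line,
#' and a machine-readable manifest records versions, seeds and a
#' parameter hash so a rerun with the same seed is byte-identical.
#'
#' @param cfg A [sim_config()] (simulated input), or `NULL` when `depths`
#'   is given.
#' @param outdir Output directory (created if needed).
#' @param depths Optional pre-loaded pool-depth tibble; skips simulation.
#' @param gene_models Optional list of [gene_model()] objects for effect
#'   annotation of the top interval.
#' @param window_bp,step_bp,filter_threshold,n_reps,confidence Scan
#'   settings (see [scan_pool_depths()]).
#' @param min_size_diff Marker-design threshold (see
#'   [design_indel_markers()]).
#' @param n_recomb Recombinants simulated for the fine-mapping stage.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the stage results (`study`, `scan`,
#'   `markers`, `panel`, `mapped`, `annotations`) and `outdir`.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir, depths = NULL,
                         gene_models = NULL, window_bp = 50000,
                         step_bp = 5000, filter_threshold = 0.3,
                         n_reps = 1000, confidence = 0.95,
                         min_size_diff = 4, n_recomb = 9, quiet = FALSE) {
  abort_if(step_bp <= 0 || window_bp < step_bp, "invalid window/step")
  abort_if(confidence <= 0 || confidence >= 1, "invalid confidence")
  abort_if(is.null(cfg) && is.null(depths),
           "need a sim_config or a depths table")
  if (!is.null(cfg)) validate_sim_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  seed <- if (!is.null(cfg)) cfg$seed else 1L

  study <- NULL
  if (is.null(depths)) {
    study <- simulate_bsa_study(cfg, genome = TRUE)
    depths <- study$depths
    write_variants_vcf(study$sites, file.path(outdir, "parent_variants.vcf"))
    write_phenotypes(study$pop$pheno, file.path(outdir, "phenotypes.tsv"))
    write_pool_depths(depths, file.path(outdir, "pool_depths.tsv"))
    write_sim_config(cfg, file.path(outdir, "config.yaml"))
    say("simulate", "%d sites, %d individuals, bulks %d/%d",
        nrow(study$sites), cfg$pop_size, length(study$bulks$low),
        length(study$bulks$high))
  }

  scan <- scan_pool_depths(
    depths, bulk_size = if (!is.null(cfg)) cfg$bulk_size else 30L,
    window_bp = window_bp, step_bp = step_bp,
    filter_threshold = filter_threshold, n_reps = n_reps,
    confidence = confidence, seed = seed,
    chrom_lengths = if (!is.null(cfg)) cfg$chrom_lengths else NULL)
  write_scan_tsv(scan$windows, file.path(outdir, "scan_windows.tsv"))
  write_intervals_bed(scan$intervals, file.path(outdir, "candidate_intervals.bed"))
  say("scan", "%d windows, %d significant, %d interval(s)",
      nrow(scan$windows), sum(scan$windows$significant, na.rm = TRUE),
      nrow(scan$intervals))

  markers <- NULL; panel <- NULL; mapped <- NULL; annotations <- NULL
  if (nrow(scan$intervals) > 0) {
    top <- scan$intervals[which.max(abs(scan$intervals$peak_delta)), ]
    if (!is.null(study) && !is.null(study$genome)) {
      top_clipped <- top
      top_clipped$end <- min(top$end, cfg$chrom_lengths[[top$chrom]])
      markers <- design_indel_markers(study$sites, top_clipped, study$genome,
                                      min_size_diff = min_size_diff)
      write_markers(markers, file.path(outdir, "indel_markers.tsv"),
                    file.path(outdir, "indel_marker_flanks.fasta"))
      say("markers", "%d InDel marker(s) in %s:%d-%d", nrow(markers),
          top$chrom, top$start, top_clipped$end)
      if (nrow(markers) >= 2) {
        truth <- study$pop$qtl$site_pos %||%
          mean(c(top$start, top_clipped$end))
        truth <- min(max(truth, min(markers$pos)), max(markers$pos))
        panel <- simulate_recombinant_panel(markers, truth, n_recomb,
                                            seed = stage_seed(cfg, "panel"))
        write_recombinant_table(panel, file.path(outdir, "recombinants.tsv"))
        mapped <- substitution_map(panel, qtl_model = "donor_low")
        readr::write_tsv(dplyr::select(mapped, -"supporting_recombinants"),
                         file.path(outdir, "mapped_interval.tsv"))
        say("finemap", "narrowed to %s:%d-%d (%s-%s)", mapped$chrom,
            mapped$start, mapped$end, mapped$left_marker,
            mapped$right_marker)
      }
    }
    if (!is.null(gene_models) && !is.null(study)) {
      in_top <- dplyr::filter(study$sites, .data$chrom == top$chrom,
                              .data$pos >= top$start, .data$pos <= top$end)
      annotations <- classify_variants(in_top, gene_models, study$genome)
      readr::write_tsv(annotations, file.path(outdir, "annotations.tsv"))
      say("annotate", "%d annotation(s), %d candidate gene(s)",
          nrow(annotations),
          sum(select_candidate_genes(annotations)$candidate))
    }
  }

  manifest <- list(
    package = "bsaqtl",
    version = as.character(utils::packageVersion("bsaqtl")),
    r_version = as.character(getRversion()),
    seed = seed,
    param_hash = rlang::hash(list(window_bp, step_bp, filter_threshold,
                                  n_reps, confidence, min_size_diff,
                                  if (!is.null(cfg)) unclass(cfg))),
    stages = c("simulate"[!is.null(study)], "scan",
               "markers"[!is.null(markers)], "finemap"[!is.null(mapped)],
               "annotate"[!is.null(annotations)]),
    n_sites = nrow(depths), n_windows = nrow(scan$windows),
    n_intervals = nrow(scan$intervals)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(study = study, scan = scan, markers = markers,
                 panel = panel, mapped = mapped,
                 annotations = annotations, outdir = outdir))
}
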