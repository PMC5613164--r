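#' Simulation configuration for an in-silico QTL-seq study
#'
#' Bundles every parameter of the synthetic study: the genome, the marker
#' density, the planted QTL, the phenotype model, the population and bulk
#' design, and the pooled-sequencing model. Defaults describe the study this
#' package emulates: a biparental rice F2 of 280 individuals phenotyped for
#' nitrogen-use efficiency (NUE, percent), bulks of the 30 lowest and 30
#' highest individuals, and ~50x pooled sequencing. The donor allele lowers
#' NUE by default (`qtl_additive_effect = -5`), so the low-NUE bulk is
#' enriched for donor alleles at the QTL.
#'
#' @param chrom_lengths Named integer vector, chromosome name -> length (bp).
#' @param variant_density Expected parental variant sites per bp.
#' @param indel_fraction Fraction of variant sites that are InDels, in
#'   `[0, 1]`.
#' @param qtl_chrom Chromosome carrying the planted QTL.
#' @param qtl_pos QTL position (bp); snapped to the nearest simulated site.
#' @param qtl_additive_effect NUE percentage points added per donor allele
#'   copy (negative: donor allele lowers NUE).
#' @param qtl_dominance Extra NUE percentage points for heterozygotes.
#' @param phenotype_mean Population mean NUE (percent).
#' @param phenotype_sd_env SD of the environmental (non-QTL) noise (percent).
#' @param pop_size Number of F2 individuals.
#' @param bulk_size Individuals per extreme bulk.
#' @param mean_depth Mean pooled sequencing depth per site per pool (reads).
#' @param seq_error_rate Per-read probability of reporting the wrong allele.
#' @param cm_per_kb Genetic map density (centimorgan per kb); default 0.004
#'   (~1 cM / 250 kb), uniform along each chromosome.
#' @param seed Integer master seed. Stage streams are derived by fixed
#'   offsets so each stage is independently reproducible.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$pop_size
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 10e6L, chr2 = 10e6L),
                       variant_density = 5e-4,
                       indel_fraction = 0.12,
                       qtl_chrom = "chr1",
                       qtl_pos = 5e6L,
                       qtl_additive_effect = -5,
                       qtl_dominance = 0,
                       phenotype_mean = 18.05,
                       phenotype_sd_env = 7,
                       pop_size = 280L,
                       bulk_size = 30L,
                       mean_depth = 50,
                       seq_error_rate = 0.001,
                       cm_per_kb = 0.004,
                       seed = 1L) {
  cfg <- list(
    chrom_lengths = chrom_lengths, variant_density = variant_density,
    indel_fraction = indel_fraction, qtl_chrom = qtl_chrom,
    qtl_pos = as.numeric(qtl_pos), qtl_additive_effect = qtl_additive_effect,
    qtl_dominance = qtl_dominance, phenotype_mean = phenotype_mean,
    phenotype_sd_env = phenotype_sd_env, pop_size = as.integer(pop_size),
    bulk_size = as.integer(bulk_size), mean_depth = mean_depth,
    seq_error_rate = seq_error_rate, cm_per_kb = cm_per_kb,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  abort_if(length(cfg$chrom_lengths) == 0, "no genome defined")
  abort_if(is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == ""),
           "chromosomes must be named")
  abort_if(any(cfg$chrom_lengths <= 0), "chromosome lengths must be positive")
  abort_if(cfg$variant_density < 0, "variant_density must be >= 0")
  abort_if(cfg$indel_fraction < 0 || cfg$indel_fraction > 1,
           "indel_fraction must be in [0, 1]")
  abort_if(!cfg$qtl_chrom %in% names(cfg$chrom_lengths),
           sprintf("QTL chromosome '%s' absent from genome", cfg$qtl_chrom))
  abort_if(cfg$qtl_pos < 1 || cfg$qtl_pos > cfg$chrom_lengths[[cfg$qtl_chrom]],
           "qtl_pos outside its chromosome")
  abort_if(2L * cfg$bulk_size > cfg$pop_size,
           "2 * bulk_size must not exceed pop_size")
  abort_if(cfg$bulk_size < 0 || cfg$pop_size < 0, "sizes must be non-negative")
  abort_if(cfg$mean_depth < 0 || cfg$seq_error_rate < 0 ||
             cfg$seq_error_rate > 1, "invalid sequencing parameters")
  abort_if(cfg$cm_per_kb < 0, "cm_per_kb must be >= 0")
  abort_if(cfg$phenotype_sd_env < 0, "phenotype_sd_env must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genome:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  cat("  QTL:", x$qtl_chrom, "@", format(x$qtl_pos, big.mark = ","),
      " a =", x$qtl_additive_effect, " d =", x$qtl_dominance, "\n")
  cat("  population:", x$pop_size, "F2; bulks", x$bulk_size, "/", x$bulk_size, "\n")
  cat("  depth:", x$mean_depth, "x; seed:", x$seed, "\n")
  invisible(x)
}

# fixed per-stage seed offsets (design: one master seed, independent streams)
seed_offsets <- c(genome = 11L, variants = 23L, population = 37L,
                  phenotypes = 53L, depths_low = 71L, depths_high = 89L,
                  panel = 101L)

stage_seed <- function(cfg, stage) {
  (cfg$seed + seed_offsets[[stage]]) %% .Machine$integer.max
}

#' Read a simulation configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly rather than silently
#' falling back to defaults.
#'
#' @param path Path to a YAML file whose keys match [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  abort_if(length(bad) > 0,
           paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  if (!is.null(raw$chrom_lengths)) raw$chrom_lengths <- unlist(raw$chrom_lengths)
  do.call(sim_config, raw)
}

#' Write a simulation configuration to YAML
#'
#' @param cfg A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.numeric(v) && is.null(names(v))) unname(v) else as.list(v)), path)
  invisible(path)
}
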