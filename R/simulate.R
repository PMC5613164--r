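#' Simulate a reference genome
#'
#' Draws a random nucleotide sequence for every chromosome in the
#' configuration. Used as the coordinate backbone for variant alleles and
#' marker flanking sequences.
#'
#' @param cfg A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_reference_genome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(stage_seed(cfg, "genome"), {
    seqs <- vapply(cfg$chrom_lengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate biallelic variant sites between two parents
#'
#' Stands in for the whole-genome comparison of a donor against a recipient
#' (reference) parent. Site counts per chromosome are Poisson with mean
#' `variant_density * length`; positions are uniform; each site is a SNP or
#' an InDel according to `indel_fraction`. When a reference genome is
#' supplied, reference alleles are read from it so flank extraction and
#' coding-sequence work stay consistent; otherwise reference bases are
#' random.
#'
#' @param cfg A [sim_config()].
#' @param genome Optional [Biostrings::DNAStringSet] from
#'   [simulate_reference_genome()].
#' @param max_indel_bp Maximum simulated InDel length difference (bp).
#' @return A tibble with `chrom`, `pos` (1-based), `ref`, `alt`, `kind`
#'   (`"SNP"` or `"InDel"`), sorted by (chrom, pos).
#' @export
simulate_parent_variants <- function(cfg, genome = NULL, max_indel_bp = 10L) {
  validate_sim_config(cfg)
  bases <- c("A", "C", "G", "T")
  with_seed(stage_seed(cfg, "variants"), {
    per_chrom <- purrr::imap(cfg$chrom_lengths, function(len, chrom) {
      n <- stats::rpois(1, cfg$variant_density * len)
      n <- min(n, len)
      if (n == 0) return(NULL)
      # keep deletions clear of the chromosome end
      pos <- sort(sample.int(max(len - max_indel_bp - 1L, 1L), n))
      is_indel <- stats::runif(n) < cfg$indel_fraction
      ref_base <- if (!is.null(genome)) {
        strsplit(as.character(Biostrings::subseq(
          genome[[chrom]], min(pos), max(pos))), "")[[1]][pos - min(pos) + 1L]
      } else sample(bases, n, replace = TRUE)
      alt <- vapply(seq_len(n), function(i) {
        if (!is_indel[i]) sample(setdiff(bases, ref_base[i]), 1)
        else ref_base[i]  # placeholder, filled below
      }, character(1))
      ref <- ref_base
      if (any(is_indel)) {
        sz <- sample.int(max_indel_bp, sum(is_indel), replace = TRUE)
        ins <- stats::runif(sum(is_indel)) < 0.5
        j <- 0L
        for (i in which(is_indel)) {
          j <- j + 1L
          if (ins[j]) {  # insertion: alt longer
            alt[i] <- paste0(ref_base[i],
                             paste(sample(bases, sz[j], replace = TRUE),
                                   collapse = ""))
          } else {       # deletion: ref longer, taken from the genome if given
            del <- if (!is.null(genome)) {
              as.character(Biostrings::subseq(genome[[chrom]], pos[i],
                                              pos[i] + sz[j]))
            } else paste(c(ref_base[i],
                           sample(bases, sz[j], replace = TRUE)), collapse = "")
            ref[i] <- del
            alt[i] <- substr(del, 1, 1)
          }
        }
      }
      tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     kind = ifelse(is_indel, "InDel", "SNP"))
    })
    out <- dplyr::bind_rows(per_chrom)
    if (nrow(out) == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            kind = character()))
    }
    dplyr::arrange(out, .data$chrom, .data$pos) |>
      dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  })
}

#' Simulate an F2 population from a biparental cross
#'
#' Each individual receives two gametes drawn independently from an F1
#' parent. Per gamete and chromosome, the crossover count is Poisson over
#' the chromosome's genetic length (`cm_per_kb`, Haldane model: no
#' interference, uniform crossover positions) and the starting parental
#' phase is random, giving the expected 1:2:1 (RR:RD:DD) genotype ratio at
#' every site.
#'
#' @param cfg A [sim_config()].
#' @param sites Variant sites from [simulate_parent_variants()].
#' @return An object of class `f2_pop`: a list with `geno` (integer matrix,
#'   individuals x sites, donor-allele dosage 0/1/2), `sites`, `ids`, and
#'   `config`. Use [tidy()] for a long tibble view.
#' @export
simulate_f2_population <- function(cfg, sites) {
  validate_sim_config(cfg)
  stopifnot(is.data.frame(sites))
  if (nrow(sites) > 0) {
    abort_if(!identical(order(sites$chrom, sites$pos), seq_len(nrow(sites))),
             "sites must be sorted by (chrom, pos)")
  }
  n <- cfg$pop_size
  ids <- sprintf("F2_%04d", seq_len(n))
  geno <- matrix(0L, nrow = n, ncol = nrow(sites),
                 dimnames = list(ids, NULL))
  with_seed(stage_seed(cfg, "population"), {
    for (chrom in names(cfg$chrom_lengths)) {
      idx <- which(sites$chrom == chrom)
      if (length(idx) == 0) next
      pos <- sites$pos[idx]
      len <- cfg$chrom_lengths[[chrom]]
      morgans <- cfg$cm_per_kb * (len / 1000) / 100
      for (g in 1:2) {
        for (i in seq_len(n)) {
          geno[i, idx] <- geno[i, idx] + gamete_alleles(pos, len, morgans)
        }
      }
    }
    structure(list(geno = geno, sites = sites, ids = ids, config = cfg,
                   pheno = NULL, qtl = NULL),
              class = "f2_pop")
  })
}

# donor-allele (0/1) vector for one gamete along one chromosome
gamete_alleles <- function(pos, len, morgans) {
  start <- stats::rbinom(1, 1, 0.5)
  k <- stats::rpois(1, morgans)
  if (k == 0) return(rep.int(start, length(pos)))
  bp <- sort(stats::runif(k, 0, len))
  (start + findInterval(pos, bp)) %% 2L
}

#' @export
print.f2_pop <- function(x, ...) {
  cat("<f2_pop>", nrow(x$geno), "individuals x", ncol(x$geno), "sites;",
      if (is.null(x$pheno)) "no phenotypes yet" else "phenotyped", "\n")
  invisible(x)
}

#' Assign single-QTL phenotypes to an F2 population
#'
#' NUE (percent) is modelled as
#' `mean + a * (dosage - 1) + d * [heterozygote] + Normal(0, sd_env)`,
#' where `dosage` is the donor-allele count at the simulated site nearest
#' the configured QTL position. With the default negative additive effect
#' the donor allele lowers NUE, so low-NUE individuals are donor-enriched.
#'
#' @param pop An `f2_pop`.
#' @param qtl Optional list overriding the QTL (`chrom`, `pos`,
#'   `additive_effect`, `dominance`); defaults come from the population's
#'   configuration.
#' @return The `f2_pop` with a `pheno` tibble (`id`, `nue`) and a `qtl`
#'   record naming the site actually used.
#' @export
assign_phenotypes <- function(pop, qtl = NULL) {
  stopifnot(inherits(pop, "f2_pop"))
  cfg <- pop$config
  qtl <- list(
    chrom = qtl$chrom %||% cfg$qtl_chrom,
    pos = qtl$pos %||% cfg$qtl_pos,
    additive_effect = qtl$additive_effect %||% cfg$qtl_additive_effect,
    dominance = qtl$dominance %||% cfg$qtl_dominance
  )
  abort_if(!qtl$chrom %in% names(cfg$chrom_lengths),
           sprintf("QTL chromosome '%s' absent from genome", qtl$chrom))
  idx <- which(pop$sites$chrom == qtl$chrom)
  abort_if(length(idx) == 0, "no simulated sites on the QTL chromosome")
  site_i <- idx[which.min(abs(pop$sites$pos[idx] - qtl$pos))]
  dos <- pop$geno[, site_i]
  with_seed(stage_seed(cfg, "phenotypes"), {
    nue <- cfg$phenotype_mean +
      qtl$additive_effect * (dos - 1) +
      qtl$dominance * (dos == 1) +
      stats::rnorm(length(dos), 0, cfg$phenotype_sd_env)
    pop$pheno <- tibble::tibble(id = pop$ids, nue = nue)
    pop$qtl <- c(qtl, list(site_index = site_i,
                           site_pos = pop$sites$pos[site_i]))
    pop
  })
}

#' Select extreme-phenotype bulks
#'
#' Picks the `k` lowest- and `k` highest-phenotype individuals. Ties are
#' broken by ascending id, so selection is stable and the two bulks are
#' always disjoint.
#'
#' @param pheno A data frame with `id` and `nue`, or an `f2_pop` with
#'   phenotypes assigned.
#' @param k Bulk size (default 30).
#' @return A list with character vectors `low` and `high` (ids, ordered from
#'   most extreme inward is not guaranteed; ordered by rank).
#' @export
select_bulks <- function(pheno, k = 30L) {
  if (inherits(pheno, "f2_pop")) {
    abort_if(is.null(pheno$pheno), "assign phenotypes before selecting bulks")
    pheno <- pheno$pheno
  }
  stopifnot(all(c("id", "nue") %in% names(pheno)))
  n <- nrow(pheno)
  abort_if(2L * k > n, sprintf("2k = %d exceeds population size %d", 2L * k, n))
  if (k == 0) return(list(low = character(), high = character()))
  ord <- order(pheno$nue, pheno$id)
  list(low = pheno$id[utils::head(ord, k)],
       high = pheno$id[utils::tail(ord, k)])
}

#' Simulate pooled sequencing depths for one bulk
#'
#' At each site the bulk's true donor-allele frequency is
#' `p = sum(dosage) / (2 * bulk size)`; total depth is Poisson with the
#' configured mean, and donor-supporting reads are Binomial(depth, p'),
#' where `p' = p(1 - e) + (1 - p)e` folds in the per-read error rate `e`.
#'
#' @param pop An `f2_pop`.
#' @param bulk_ids Character vector of member ids.
#' @param which_bulk `"low"` or `"high"`; selects the stage RNG stream so
#'   the two pools are independent but individually reproducible.
#' @return A tibble `chrom`, `pos`, `ref_count`, `alt_count` (alt = donor).
#' @export
simulate_pool_depths <- function(pop, bulk_ids, which_bulk = c("low", "high")) {
  stopifnot(inherits(pop, "f2_pop"))
  which_bulk <- match.arg(which_bulk)
  abort_if(length(bulk_ids) == 0, "bulk is empty")
  abort_if(!all(bulk_ids %in% pop$ids), "unknown individual id in bulk")
  cfg <- pop$config
  g <- pop$geno[bulk_ids, , drop = FALSE]
  p <- colSums(g) / (2 * length(bulk_ids))
  e <- cfg$seq_error_rate
  p_obs <- p * (1 - e) + (1 - p) * e
  stage <- if (which_bulk == "low") "depths_low" else "depths_high"
  with_seed(stage_seed(cfg, stage), {
    depth <- stats::rpois(length(p), cfg$mean_depth)
    alt <- stats::rbinom(length(p), depth, p_obs)
    tibble::tibble(chrom = pop$sites$chrom, pos = pop$sites$pos,
                   ref_count = depth - alt, alt_count = alt)
  })
}

#' Simulate pooled depths for both extreme bulks
#'
#' Convenience wrapper over [simulate_pool_depths()] producing the wide
#' low/high table consumed by the SNP-index scan.
#'
#' @param pop An `f2_pop` with phenotypes.
#' @param bulks A list with `low` and `high` id vectors, from
#'   [select_bulks()].
#' @return A tibble `chrom`, `pos`, `ref_count_L`, `alt_count_L`,
#'   `ref_count_H`, `alt_count_H`.
#' @export
simulate_bulk_depths <- function(pop, bulks = NULL) {
  bulks <- bulks %||% select_bulks(pop, pop$config$bulk_size)
  lo <- simulate_pool_depths(pop, bulks$low, "low")
  hi <- simulate_pool_depths(pop, bulks$high, "high")
  tibble::tibble(chrom = lo$chrom, pos = lo$pos,
                 ref_count_L = lo$ref_count, alt_count_L = lo$alt_count,
                 ref_count_H = hi$ref_count, alt_count_H = hi$alt_count)
}

#' Run the whole in-silico study
#'
#' Genome, parental variants, F2 population, phenotypes, bulks and pooled
#' depths in one call, each stage on its own seed stream derived from the
#' master seed.
#'
#' @param cfg A [sim_config()].
#' @param genome Simulate the reference sequence too? (needed for marker
#'   design; skip for speed when only depths are used).
#' @return A list with `config`, `genome` (or `NULL`), `sites`, `pop`,
#'   `bulks`, `depths`.
#' @export
simulate_bsa_study <- function(cfg, genome = FALSE) {
  gen <- if (genome) simulate_reference_genome(cfg) else NULL
  sites <- simulate_parent_variants(cfg, gen)
  pop <- simulate_f2_population(cfg, sites) |> assign_phenotypes()
  bulks <- select_bulks(pop, cfg$bulk_size)
  depths <- simulate_bulk_depths(pop, bulks)
  list(config = cfg, genome = gen, sites = sites, pop = pop,
       bulks = bulks, depths = depths)
}

#' Simulate a recombinant panel for substitution mapping
#'
#' Builds an error-free fixture: each recombinant carries exactly one
#' breakpoint, placed uniformly in one of the gaps between adjacent
#' markers, with homozygous recipient (R) and donor (D) segments on the two
#' sides (random orientation). The phenotype class is read off the genotype
#' at the marker nearest the true QTL: donor homozygote = `low`, recipient
#' homozygote = `high` (the donor allele lowers the trait).
#'
#' @param markers A data frame `marker_id`, `chrom`, `pos` (one chromosome),
#'   ordered or orderable by position.
#' @param truth_pos True QTL position (bp), inside the marker span.
#' @param n_recomb Number of recombinants.
#' @param seed Integer seed.
#' @return A long tibble `id`, `marker_id`, `chrom`, `pos`, `genotype`
#'   (`"R"`/`"D"`), `phenotype_class` (`"low"`/`"high"`).
#' @export
simulate_recombinant_panel <- function(markers, truth_pos, n_recomb,
                                       seed = 1L) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "chrom", "pos") %in% names(markers)))
  abort_if(nrow(markers) < 2, "need at least 2 markers")
  abort_if(length(unique(markers$chrom)) != 1,
           "markers must lie on one chromosome")
  markers <- dplyr::arrange(markers, .data$pos)
  abort_if(truth_pos < min(markers$pos) || truth_pos > max(markers$pos),
           "true QTL must lie within the marker span")
  m <- nrow(markers)
  nearest <- which.min(abs(markers$pos - truth_pos))
  if (n_recomb == 0) {
    return(tibble::tibble(id = character(), marker_id = character(),
                          chrom = character(), pos = numeric(),
                          genotype = character(), phenotype_class = character()))
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_recomb), function(r) {
      gap <- sample.int(m - 1L, 1)                 # breakpoint in gap (gap, gap+1)
      left_is_donor <- stats::runif(1) < 0.5
      geno <- ifelse(seq_len(m) <= gap,
                     if (left_is_donor) "D" else "R",
                     if (left_is_donor) "R" else "D")
      phen <- if (geno[nearest] == "D") "low" else "high"
      tibble::tibble(id = sprintf("REC_%02d", r),
                     marker_id = markers$marker_id, chrom = markers$chrom,
                     pos = markers$pos, genotype = geno,
                     phenotype_class = phen)
    })
  })
}

#' Tidy an F2 population into a long tibble
#'
#' One row per individual per site, with donor-allele dosage, genotype
#' class (`RR`/`RD`/`DD`) and, when assigned, the phenotype.
#'
#' @param x An `f2_pop`.
#' @param ... Unused.
#' @return A tibble `id`, `chrom`, `pos`, `dosage`, `genotype`, `nue`.
#' @method tidy f2_pop
#' @export
tidy.f2_pop <- function(x, ...) {
  out <- tibble::tibble(id = rep(x$ids, times = ncol(x$geno)),
                        chrom = rep(x$sites$chrom, each = nrow(x$geno)),
                        pos = rep(x$sites$pos, each = nrow(x$geno)),
                        dosage = as.integer(x$geno),
                        genotype = c("RR", "RD", "DD")[as.integer(x$geno) + 1L])
  if (!is.null(x$pheno)) out <- dplyr::left_join(out, x$pheno, by = "id")
  out
}
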