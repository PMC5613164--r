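test_that("variant simulation matches its Poisson model and tags kinds", {
  cfg0 <- sim_config(chrom_lengths = c(c1 = 1e6L), variant_density = 0,
                     qtl_chrom = "c1", qtl_pos = 1, seed = 1)
  expect_equal(nrow(simulate_parent_variants(cfg0)), 0)

  counts <- vapply(1:100, function(s) {
    cfg <- sim_config(chrom_lengths = c(c1 = 1e6L), variant_density = 1e-3,
                      qtl_chrom = "c1", qtl_pos = 1, seed = s)
    nrow(simulate_parent_variants(cfg))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1000) / 1000, 0.05)

  cfg <- sim_config(chrom_lengths = c(c1 = 1e6L), variant_density = 1e-3,
                    indel_fraction = 1, qtl_chrom = "c1", qtl_pos = 1, seed = 7)
  v <- simulate_parent_variants(cfg)
  expect_true(all(v$kind == "InDel"))
  expect_true(all(v$pos >= 1 & v$pos <= 1e6))
  expect_true(all(diff(v$pos) > 0))
  expect_true(all(nchar(v$ref) != nchar(v$alt)))
})

test_that("variant simulation is deterministic and errors on an empty genome", {
  cfg <- small_config(seed = 5)
  expect_identical(simulate_parent_variants(cfg), simulate_parent_variants(cfg))
  expect_error(sim_config(chrom_lengths = integer()), "no genome")
})

test_that("F2 genotypes follow 1:2:1 segregation and linkage block structure", {
  # no recombination: one parental block per chromosome
  cfg0 <- small_config(seed = 2, cm_per_kb = 0, pop_size = 40L, bulk_size = 5L)
  sites <- simulate_parent_variants(cfg0)
  pop0 <- simulate_f2_population(cfg0, sites)
  for (ch in unique(sites$chrom)) {
    g <- pop0$geno[, sites$chrom == ch, drop = FALSE]
    expect_true(all(apply(g, 1, function(r) length(unique(r)) == 1)))
  }

  # large population: chi-square goodness of fit to 1:2:1 at one site
  cfg <- sim_config(chrom_lengths = c(c1 = 1e5L), variant_density = 5e-5,
                    qtl_chrom = "c1", qtl_pos = 1, pop_size = 10000L,
                    bulk_size = 10L, seed = 11)
  pop <- simulate_f2_population(cfg, simulate_parent_variants(cfg))
  dos <- pop$geno[, 1]
  obs <- tabulate(dos + 1L, nbins = 3)
  expect_gt(stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value, 0.01)

  # genotype changes along a chromosome only at crossover breakpoints:
  # with two tightly linked sites, genotypes agree for every individual
  cfg2 <- small_config(seed = 3)
  two <- tibble::tibble(chrom = "chrA", pos = c(1000, 1001),
                        ref = c("A", "A"), alt = c("T", "T"),
                        kind = c("SNP", "SNP"))
  pop2 <- simulate_f2_population(cfg2, two)
  expect_equal(pop2$geno[, 1], pop2$geno[, 2])
})

test_that("phenotype model recovers its planted additive effect", {
  cfg0 <- small_config(seed = 4, qtl_additive_effect = 0, phenotype_sd_env = 0)
  st0 <- simulate_bsa_study(cfg0)
  expect_true(all(st0$pop$pheno$nue == cfg0$phenotype_mean))

  cfg1 <- small_config(seed = 4, qtl_additive_effect = 5, phenotype_sd_env = 0)
  pop1 <- assign_phenotypes(simulate_f2_population(
    cfg1, simulate_parent_variants(cfg1)))
  dos <- pop1$geno[, pop1$qtl$site_index]
  expect_equal(mean(pop1$pheno$nue[dos == 2]) - mean(pop1$pheno$nue[dos == 0]),
               10)
  # variance decomposition at sd_env = 0: Var(nue) ~ a^2 / 2
  expect_lt(abs(stats::var(pop1$pheno$nue) - 5^2 / 2), 2)

  cfg2 <- sim_config(chrom_lengths = c(c1 = 2e5L), variant_density = 1e-4,
                     qtl_chrom = "c1", qtl_pos = 1e5, qtl_additive_effect = 5,
                     phenotype_sd_env = 3, pop_size = 10000L, bulk_size = 10L,
                     seed = 12)
  pop2 <- assign_phenotypes(simulate_f2_population(
    cfg2, simulate_parent_variants(cfg2)))
  slope <- stats::coef(stats::lm(pop2$pheno$nue ~ pop2$geno[, pop2$qtl$site_index]))[2]
  expect_lt(abs(slope - 5), 0.1)
})

test_that("bulk selection takes the k extremes with stable id tie-breaks", {
  ph <- tibble::tibble(id = sprintf("i%03d", 1:280), nue = as.numeric(1:280))
  b <- select_bulks(ph, 30)
  expect_setequal(b$low, sprintf("i%03d", 1:30))
  expect_setequal(b$high, sprintf("i%03d", 251:280))
  expect_length(intersect(b$low, b$high), 0)

  tied <- tibble::tibble(id = sprintf("i%d", 1:6), nue = rep(1, 6))
  bt <- select_bulks(tied, 2)
  expect_equal(bt$low, c("i1", "i2"))
  expect_equal(bt$high, c("i5", "i6"))

  expect_equal(lengths(select_bulks(ph, 0)), c(low = 0L, high = 0L))
  expect_error(select_bulks(ph, 200), "exceeds")
})

test_that("pool depth simulation reproduces fixed allele frequencies", {
  cfg <- sim_config(chrom_lengths = c(c1 = 1e6L), variant_density = 1e-2,
                    qtl_chrom = "c1", qtl_pos = 1, pop_size = 4L,
                    bulk_size = 2L, mean_depth = 50, seq_error_rate = 0,
                    seed = 6)
  sites <- simulate_parent_variants(cfg)
  pop <- simulate_f2_population(cfg, sites)

  # bulk monomorphic recipient: donor count 0 everywhere
  pop$geno[] <- 0L
  d0 <- simulate_pool_depths(pop, pop$ids[1:2], "low")
  expect_true(all(d0$alt_count == 0))

  # bulk monomorphic donor: donor count = depth everywhere
  pop$geno[] <- 2L
  d2 <- simulate_pool_depths(pop, pop$ids[1:2], "low")
  expect_true(all(d2$ref_count == 0))

  # p = 0.5 over ~10,000 sites: mean donor fraction within CLT bound
  pop$geno[] <- 1L
  d1 <- simulate_pool_depths(pop, pop$ids[1:2], "low")
  frac <- d1$alt_count / (d1$ref_count + d1$alt_count)
  expect_lt(abs(mean(frac, na.rm = TRUE) - 0.5), 0.01)

  # error model shifts the expectation to p(1-e) + (1-p)e
  pop$geno[] <- 0L
  pop$config$seq_error_rate <- 0.01
  de <- simulate_pool_depths(pop, pop$ids[1:2], "low")
  pe <- sum(de$alt_count) / sum(de$ref_count + de$alt_count)
  se <- sqrt(0.01 * 0.99 / sum(de$ref_count + de$alt_count))
  expect_lt(abs(pe - 0.01), 3 * se)
})

test_that("the full study is byte-identical under one seed", {
  cfg <- small_config(seed = 99)
  a <- simulate_bsa_study(cfg)
  b <- simulate_bsa_study(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$pop$geno, b$pop$geno)
  expect_identical(a$pop$pheno, b$pop$pheno)
  expect_identical(a$depths, b$depths)
})

test_that("recombinant panels have one breakpoint and error-free phenotypes", {
  mk <- tibble::tibble(marker_id = sprintf("M%02d", 1:11), chrom = "c1",
                       pos = seq(1e5, 11e5, length.out = 11))
  expect_equal(nrow(simulate_recombinant_panel(mk, 5.5e5, 0)), 0)
  expect_error(simulate_recombinant_panel(mk[1, ], 1e5, 3), "at least 2")

  pan <- simulate_recombinant_panel(mk, 5.5e5, 25, seed = 8)
  per <- split(pan, pan$id)
  for (p in per) {
    p <- p[order(p$pos), ]
    expect_equal(sum(p$genotype[-1] != p$genotype[-nrow(p)]), 1)
    nearest <- p$genotype[which.min(abs(p$pos - 5.5e5))]
    expect_equal(unique(p$phenotype_class),
                 if (nearest == "D") "low" else "high")
  }

  # two markers, one recombinant: the single gap holds the breakpoint
  pan2 <- simulate_recombinant_panel(mk[1:2, ], 1.5e5, 1, seed = 3)
  expect_equal(length(unique(pan2$genotype)), 2)
})
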