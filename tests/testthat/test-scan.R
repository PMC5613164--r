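depth_row <- function(pos, rl, al, rh, ah, chrom = "c1") {
  tibble::tibble(chrom = chrom, pos = pos, ref_count_L = rl,
                 alt_count_L = al, ref_count_H = rh, alt_count_H = ah)
}

test_that("SNP-index endpoints and arithmetic follow the pooled-read definition", {
  d <- dplyr::bind_rows(depth_row(100, 10, 0, 0, 12),
                        depth_row(200, 7, 3, 3, 7),
                        depth_row(300, 0, 0, 5, 5))
  idx <- compute_snp_index(d)
  expect_equal(idx$index_L, c(0, 0.3, NA))
  expect_equal(idx$index_H, c(1, 0.7, 0.5))
  expect_equal(idx$depth_L, c(10, 10, 0))
  expect_error(compute_snp_index(depth_row(1, -1, 0, 0, 0)), "non-negative")
})

test_that("the both-pools low-index filter is strict and drops undefined sites", {
  d <- dplyr::bind_rows(
    depth_row(1, 80, 20, 75, 25),   # L .2  H .25 -> removed
    depth_row(2, 20, 80, 90, 10),   # L .8  H .1  -> kept
    depth_row(3, 70, 30, 100, 0),   # L .3  H 0   -> kept (strict <)
    depth_row(4, 0, 0, 50, 50))     # undefined L -> removed
  out <- filter_low_index(compute_snp_index(d), 0.3)
  expect_equal(out$pos, c(2, 3))
})

test_that("window means equal a brute-force oracle over all site-window pairs", {
  set.seed(31)
  n <- 180
  d <- tibble::tibble(
    chrom = sample(c("c1", "c2"), n, TRUE),
    pos = sample.int(2e5, n),
    ref_count_L = rpois(n, 25), alt_count_L = rpois(n, 25),
    ref_count_H = rpois(n, 25), alt_count_H = rpois(n, 25)) |>
    dplyr::distinct(chrom, pos, .keep_all = TRUE) |>
    dplyr::arrange(chrom, pos)
  rec <- filter_low_index(compute_snp_index(d))
  win <- window_scan(rec, window_bp = 50000, step_bp = 5000)

  for (i in sample(which(win$n_sites > 0), 25)) {
    member <- rec$chrom == win$chrom[i] &
      rec$pos >= win$start[i] & rec$pos <= win$end[i]
    expect_equal(win$n_sites[i], sum(member))
    expect_equal(win$mean_index_L[i], mean(rec$index_L[member]))
    expect_equal(win$mean_index_H[i], mean(rec$index_H[member]))
  }
  # every member site of every window is genuinely inside it
  expect_true(all(win$end - win$start + 1 == 50000))
})

test_that("window scan handles singletons, hand means, empties and bad geometry", {
  one <- compute_snp_index(depth_row(10000, 4, 6, 5, 5))
  w1 <- window_scan(one, 50000, 5000)
  cover <- w1[w1$n_sites > 0, ]
  expect_true(all(cover$start <= 10000 & cover$end >= 10000))
  expect_true(all(cover$mean_index_L == 0.6))

  two <- compute_snp_index(dplyr::bind_rows(
    depth_row(1000, 8, 2, 5, 5), depth_row(40000, 2, 8, 5, 5)))
  w2 <- window_scan(two, 50000, 5000)
  first <- w2[w2$start == 1, ]
  expect_equal(first$mean_index_L, 0.5)
  expect_equal(first$n_sites, 2)

  expect_equal(nrow(window_scan(one[0, ], 50000, 5000)), 0)
  expect_error(window_scan(one, 50000, 0), "positive")
  expect_error(window_scan(one, 1000, 5000), ">= step")
})

test_that("delta is oriented high minus low and bounded", {
  w <- window_scan(compute_snp_index(depth_row(100, 1, 9, 9, 1)), 1000, 1000)
  d <- delta_scan(w)
  expect_equal(d$delta[d$n_sites > 0], -0.8)
  flipped <- delta_scan(w, "low_minus_high")
  expect_equal(flipped$delta[flipped$n_sites > 0], 0.8)
  expect_true(all(abs(d$delta) <= 1, na.rm = TRUE))
})

test_that("null thresholds are symmetric, depth-monotone and deterministic", {
  ci <- simulate_null_thresholds(30, 50, n_reps = 10000, seed = 5)
  expect_lt(abs(ci[["ci_low"]] + ci[["ci_high"]]), 0.02)
  expect_lt(ci[["ci_low"]], 0)
  expect_gt(ci[["ci_high"]], 0)

  widths <- vapply(1:20, function(s) {
    w10 <- diff(simulate_null_thresholds(30, 10, 1000, seed = s))
    w50 <- diff(simulate_null_thresholds(30, 50, 1000, seed = s))
    c(w10 - w50)
  }, numeric(1))
  expect_gt(mean(widths), 0)

  expect_identical(simulate_null_thresholds(30, 50, seed = 2),
                   simulate_null_thresholds(30, 50, seed = 2))
  expect_error(simulate_null_thresholds(30, 50, confidence = 1.2),
               "confidence")
})

test_that("interval calling merges significant runs and applies the pool rule", {
  # hand-built window table: two significant runs split by one dull window
  w <- tibble::tibble(
    chrom = "c1", start = seq(1, by = 5000, length.out = 7),
    end = seq(50000, by = 5000, length.out = 7),
    midpoint = (start + end) / 2, n_sites = 5,
    mean_index_L = c(0.9, 0.9, 0.5, 0.9, 0.9, 0.5, 0.1),
    mean_index_H = c(0.1, 0.1, 0.5, 0.1, 0.1, 0.5, 0.9),
    mean_depth_L = 50, mean_depth_H = 50) |>
    delta_scan()
  w$ci_low <- -0.3; w$ci_high <- 0.3
  w$significant <- w$delta < w$ci_low | w$delta > w$ci_high

  iv <- call_candidate_intervals(w)
  expect_equal(nrow(iv), 3)
  expect_equal(iv$start, c(1, 15001, 30001))
  expect_true(iv$supports_pool_rule[1])   # 0.9/0.1 pattern throughout
  expect_true(iv$supports_pool_rule[3])   # mirrored window allowed
  expect_equal(iv$peak_delta[1], -0.8)

  w0 <- w; w0$delta <- 0; w0$significant <- FALSE
  expect_equal(nrow(call_candidate_intervals(w0)), 0)
})

test_that("a planted QTL is recovered by the top interval with the 0.7/0.3 signature", {
  cfg <- sim_config(seed = 17)
  st <- simulate_bsa_study(cfg)
  sc <- scan_pool_depths(st$depths, bulk_size = cfg$bulk_size,
                         seed = cfg$seed, chrom_lengths = cfg$chrom_lengths)
  expect_gt(nrow(sc$intervals), 0)
  top <- sc$intervals[which.max(abs(sc$intervals$peak_delta)), ]
  qpos <- st$pop$qtl$site_pos
  expect_equal(top$chrom, cfg$qtl_chrom)
  expect_lte(top$start, qpos)
  expect_gte(top$end, qpos)
  # donor-enriched low bulk: delta = H - L strongly negative at the QTL
  expect_lt(top$peak_delta, -0.3)
})

test_that("scan results tidy, glance and plot", {
  cfg <- small_config(seed = 23)
  st <- simulate_bsa_study(cfg)
  sc <- scan_pool_depths(st$depths, bulk_size = cfg$bulk_size, n_reps = 200,
                         seed = 1, chrom_lengths = cfg$chrom_lengths)
  td <- generics::tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("delta", "ci_low", "ci_high", "significant") %in% names(td)))
  gl <- generics::glance(sc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_windows, nrow(sc$windows))
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_snp_index(sc), "ggplot")
})

test_that("detection power is non-decreasing in the planted effect size", {
  detect <- function(effect, seeds = 1:20) {
    mean(vapply(seeds, function(s) {
      cfg <- sim_config(seed = s, qtl_additive_effect = -effect)
      st <- simulate_bsa_study(cfg)
      sc <- scan_pool_depths(st$depths, bulk_size = cfg$bulk_size,
                             n_reps = 500, seed = s,
                             chrom_lengths = cfg$chrom_lengths)
      qpos <- st$pop$qtl$site_pos
      iv <- sc$intervals
      any(iv$chrom == cfg$qtl_chrom & iv$start <= qpos & iv$end >= qpos)
    }, logical(1)))
  }
  power <- vapply(c(0, 2.5, 5, 10), detect, numeric(1))
  # allow one seed of Monte-Carlo slack per step
  expect_true(all(diff(power) >= -0.05))
  expect_lt(power[1], 0.5)
  expect_gt(power[4], 0.9)
})
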