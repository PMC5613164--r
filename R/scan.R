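#' Per-site SNP-index for both pools
#'
#' The SNP-index at a site is the fraction of a pool's reads carrying the
#' donor (alt) allele: 0 when every read matches the recipient/reference
#' parent, 1 when every read differs. Pools with zero depth at a site get
#' `NA` and are excluded downstream.
#'
#' @param depths A data frame `chrom`, `pos`, `ref_count_L`, `alt_count_L`,
#'   `ref_count_H`, `alt_count_H` (L = low-phenotype pool, H = high).
#' @return A tibble adding `depth_L`, `depth_H`, `index_L`, `index_H`.
#' @examples
#' compute_snp_index(data.frame(chrom = "chr1", pos = 100,
#'   ref_count_L = 7, alt_count_L = 3, ref_count_H = 0, alt_count_H = 12))
#' @export
compute_snp_index <- function(depths) {
  need <- c("chrom", "pos", "ref_count_L", "alt_count_L",
            "ref_count_H", "alt_count_H")
  stopifnot(all(need %in% names(depths)))
  cnt <- depths[, need[-(1:2)]]
  abort_if(any(unlist(cnt) < 0), "read counts must be non-negative")
  out <- tibble::as_tibble(depths)
  out$depth_L <- out$ref_count_L + out$alt_count_L
  out$depth_H <- out$ref_count_H + out$alt_count_H
  out$index_L <- ifelse(out$depth_L > 0, out$alt_count_L / out$depth_L, NA_real_)
  out$index_H <- ifelse(out$depth_H > 0, out$alt_count_H / out$depth_H, NA_real_)
  out
}

#' Filter sites with low SNP-index in both pools
#'
#' Drops sites whose SNP-index is below `threshold` in *both* pools
#' (strict `<`), the standard QTL-seq filter against shared homozygous or
#' spurious calls, along with sites undefined (zero depth) in either pool.
#' Order is preserved.
#'
#' @param records Output of [compute_snp_index()].
#' @param threshold Both-pools index threshold (default 0.3).
#' @return The filtered tibble.
#' @export
filter_low_index <- function(records, threshold = 0.3) {
  stopifnot(all(c("index_L", "index_H") %in% names(records)))
  keep <- !is.na(records$index_L) & !is.na(records$index_H) &
    !(records$index_L < threshold & records$index_H < threshold)
  records[keep, , drop = FALSE]
}

#' Sliding-window means of the SNP-index
#'
#' Per chromosome, windows of `window_bp` start every `step_bp` (window k
#' covers 1-based positions `k*step + 1 ... k*step + window`). Each
#' window's pool means are unweighted arithmetic means over its member
#' sites; windows with no sites carry `NA` means and are excluded from
#' interval calling. Windows are reported with their midpoint.
#'
#' @param records Filtered SNP-index records, sorted by (chrom, pos).
#' @param window_bp Window size in bp (default 50000).
#' @param step_bp Step in bp (default 5000).
#' @param chrom_lengths Optional named lengths; defaults to the largest
#'   observed position per chromosome.
#' @return A tibble `chrom`, `start`, `end` (1-based inclusive), `midpoint`,
#'   `n_sites`, `mean_index_L`, `mean_index_H`, `mean_depth_L`,
#'   `mean_depth_H`.
#' @export
window_scan <- function(records, window_bp = 50000, step_bp = 5000,
                        chrom_lengths = NULL) {
  abort_if(step_bp <= 0, "step_bp must be positive")
  abort_if(window_bp < step_bp, "window_bp must be >= step_bp")
  cols <- c("chrom", "start", "end", "midpoint", "n_sites",
            "mean_index_L", "mean_index_H", "mean_depth_L", "mean_depth_H")
  if (nrow(records) == 0) {
    return(tibble::as_tibble(stats::setNames(
      as.list(c(list(character()), rep(list(numeric()), 8))), cols)))
  }
  records <- dplyr::arrange(tibble::as_tibble(records), .data$chrom, .data$pos)
  chroms <- unique(records$chrom)
  lens <- if (is.null(chrom_lengths)) {
    tapply(records$pos, records$chrom, max)[chroms]
  } else chrom_lengths[chroms]
  grids <- purrr::map_dfr(chroms, function(ch) {
    starts0 <- seq(0, max(lens[[ch]] - 1, 0), by = step_bp)
    tibble::tibble(chrom = ch, start = starts0 + 1,
                   end = starts0 + window_bp)
  })
  # each site at pos belongs to windows with 0-based start in
  # [pos - window, pos - 1] on the step grid
  kmin <- pmax(ceiling((records$pos - window_bp) / step_bp), 0)
  kmax <- floor((records$pos - 1) / step_bp)
  nk <- pmax(kmax - kmin + 1, 0)
  memb <- tibble::tibble(
    chrom = rep(records$chrom, nk),
    start = unlist(purrr::map2(kmin, kmax, function(a, b)
      if (b >= a) seq(a, b) else numeric(0))) * step_bp + 1,
    index_L = rep(records$index_L, nk),
    index_H = rep(records$index_H, nk),
    depth_L = rep(records$depth_L, nk),
    depth_H = rep(records$depth_H, nk)
  )
  agg <- memb |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     mean_index_L = mean(.data$index_L),
                     mean_index_H = mean(.data$index_H),
                     mean_depth_L = mean(.data$depth_L),
                     mean_depth_H = mean(.data$depth_H), .groups = "drop")
  grids |>
    dplyr::left_join(agg, by = c("chrom", "start")) |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
                  midpoint = (.data$start + .data$end) / 2) |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Populate delta(SNP-index) on a window scan
#'
#' delta(SNP-index) is the difference of the windowed SNP-index between the
#' two extreme bulks. The default orientation is high-phenotype minus
#' low-phenotype pool; it deviates from 0 near a QTL.
#'
#' @param windows Output of [window_scan()].
#' @param orientation `"high_minus_low"` (default) or `"low_minus_high"`.
#' @return The windows with a `delta` column.
#' @export
delta_scan <- function(windows, orientation = c("high_minus_low",
                                                "low_minus_high")) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("mean_index_L", "mean_index_H") %in% names(windows)))
  d <- windows$mean_index_H - windows$mean_index_L
  windows$delta <- if (orientation == "high_minus_low") d else -d
  windows
}

#' Monte-Carlo null thresholds for delta(SNP-index)
#'
#' Simulates the no-QTL sampling distribution of a single-site delta:
#' per replicate and pool, a bulk of `bulk_size` F2 individuals each
#' contributes 0/1/2 donor alleles with probability 1/4, 1/2, 1/4
#' (equivalently the bulk's `2 * bulk_size` alleles are iid Bernoulli(1/2),
#' which is how it is drawn), the observed index is
#' `Binomial(depth, p) / depth`, and the null delta is the difference of
#' the two pools' indices. Bounds are the empirical two-sided quantiles at
#' the requested confidence (order statistics, linear interpolation).
#'
#' @param bulk_size Individuals per bulk.
#' @param depth Read depth per pool (rounded to an integer >= 1).
#' @param n_reps Replicates (default 1000).
#' @param confidence Two-sided confidence level in (0, 1) (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric `c(ci_low, ci_high)`.
#' @export
simulate_null_thresholds <- function(bulk_size, depth, n_reps = 1000,
                                     confidence = 0.95, seed = 1L) {
  abort_if(confidence <= 0 || confidence >= 1,
           "confidence must be in (0, 1)")
  abort_if(bulk_size < 1, "bulk_size must be >= 1")
  depth <- max(1L, as.integer(round(depth)))
  n_all <- 2L * as.integer(bulk_size)
  with_seed(seed, {
    idx <- function() {
      p <- stats::rbinom(n_reps, n_all, 0.5) / n_all
      stats::rbinom(n_reps, depth, p) / depth
    }
    delta <- idx() - idx()
    q <- stats::quantile(delta, c((1 - confidence) / 2,
                                  1 - (1 - confidence) / 2),
                         names = FALSE, type = 7)
    c(ci_low = q[1], ci_high = q[2])
  })
}

#' Attach per-window null thresholds and significance
#'
#' Thresholds are depth-dependent, so each window uses the null bounds for
#' its own mean observed depth (the two pools' window mean depths averaged
#' and rounded); bounds are cached per distinct depth. A window is
#' significant when its delta falls outside `[ci_low, ci_high]`.
#'
#' @param windows Output of [delta_scan()].
#' @param bulk_size Individuals per bulk.
#' @param n_reps,confidence,seed Passed to [simulate_null_thresholds()];
#'   each distinct depth gets a seed offset by that depth so results do not
#'   depend on window order.
#' @return Windows with `ci_low`, `ci_high`, `significant` columns.
#' @export
add_null_thresholds <- function(windows, bulk_size, n_reps = 1000,
                                confidence = 0.95, seed = 1L) {
  stopifnot("delta" %in% names(windows))
  wdepth <- round((windows$mean_depth_L + windows$mean_depth_H) / 2)
  uniq <- sort(unique(wdepth[!is.na(wdepth) & wdepth >= 1]))
  ci <- purrr::map(uniq, function(d)
    simulate_null_thresholds(bulk_size, d, n_reps, confidence,
                             seed = seed + d))
  names(ci) <- as.character(uniq)
  windows$ci_low <- NA_real_
  windows$ci_high <- NA_real_
  ok <- !is.na(wdepth) & wdepth >= 1
  windows$ci_low[ok] <- vapply(as.character(wdepth[ok]),
                               function(k) ci[[k]][["ci_low"]], numeric(1))
  windows$ci_high[ok] <- vapply(as.character(wdepth[ok]),
                                function(k) ci[[k]][["ci_high"]], numeric(1))
  windows$significant <- !is.na(windows$delta) & ok &
    (windows$delta < windows$ci_low | windows$delta > windows$ci_high)
  windows
}

#' Call candidate QTL intervals from a thresholded scan
#'
#' Merges maximal runs of consecutive significant windows (consecutive in
#' the sliding-window grid, hence genomically overlapping) into candidate
#' intervals; any intervening non-significant or empty window breaks a
#' run. Each interval records whether every member window shows the strong
#' pooled signature (low-pool mean index >= `l_pool_min` and high-pool
#' <= `h_pool_max`, or the mirrored pattern).
#'
#' @param windows Output of [add_null_thresholds()].
#' @param l_pool_min,h_pool_max Pool-signature bounds (defaults 0.7 / 0.3).
#' @return A tibble `chrom`, `start`, `end`, `n_windows`, `peak_delta`
#'   (signed delta of largest magnitude), `supports_pool_rule`, sorted by
#'   (chrom, start).
#' @export
call_candidate_intervals <- function(windows, l_pool_min = 0.7,
                                     h_pool_max = 0.3) {
  stopifnot(all(c("delta", "ci_low", "ci_high", "significant")
                %in% names(windows)))
  w <- dplyr::arrange(tibble::as_tibble(windows), .data$chrom, .data$start)
  ok <- w$significant & w$n_sites > 0
  ok[is.na(ok)] <- FALSE
  # run id advances at every chromosome change or significance change
  brk <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] | ok[-1] != ok[-nrow(w)])
  w$run <- cumsum(brk)
  sig <- w[ok, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          peak_delta = numeric(),
                          supports_pool_rule = logical()))
  }
  sig |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(),
      peak_delta = .data$delta[which.max(abs(.data$delta))],
      supports_pool_rule = all(
        (.data$mean_index_L >= l_pool_min & .data$mean_index_H <= h_pool_max) |
          (.data$mean_index_L <= h_pool_max & .data$mean_index_H >= l_pool_min)),
      .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Full SNP-index scan of a pooled-depth table
#'
#' The complete QTL-seq statistic in one call: per-site SNP-index, the
#' both-pools low-index filter, sliding-window means, delta(SNP-index),
#' depth-matched Monte-Carlo null thresholds, and candidate-interval
#' calling.
#'
#' @param depths Pool-depth table (see [compute_snp_index()]).
#' @param bulk_size Individuals per bulk (default 30).
#' @param window_bp,step_bp Window geometry (defaults 50 kb / 5 kb).
#' @param filter_threshold Both-pools SNP-index filter (default 0.3).
#' @param n_reps,confidence Null-simulation settings (1000 reps, 95%).
#' @param seed Integer seed for the null simulation.
#' @param chrom_lengths Optional named chromosome lengths for the window
#'   grid.
#' @param orientation Delta orientation, see [delta_scan()].
#' @return A `bsa_scan` object: list with `windows`, `intervals`, `sites`
#'   (filtered per-site records) and `params`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
scan_pool_depths <- function(depths, bulk_size = 30L, window_bp = 50000,
                             step_bp = 5000, filter_threshold = 0.3,
                             n_reps = 1000, confidence = 0.95, seed = 1L,
                             chrom_lengths = NULL,
                             orientation = "high_minus_low") {
  sites <- compute_snp_index(depths) |>
    filter_low_index(filter_threshold)
  windows <- window_scan(sites, window_bp, step_bp, chrom_lengths) |>
    delta_scan(orientation) |>
    add_null_thresholds(bulk_size, n_reps, confidence, seed)
  intervals <- call_candidate_intervals(windows)
  structure(list(windows = windows, intervals = intervals, sites = sites,
                 params = list(bulk_size = bulk_size, window_bp = window_bp,
                               step_bp = step_bp,
                               filter_threshold = filter_threshold,
                               n_reps = n_reps, confidence = confidence,
                               seed = seed, orientation = orientation)),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  n_def <- sum(x$windows$n_sites > 0)
  cat("<bsa_scan>", nrow(x$sites), "sites;", nrow(x$windows), "windows (",
      n_def, "non-empty );", sum(x$windows$significant, na.rm = TRUE),
      "significant;", nrow(x$intervals), "candidate interval(s)\n")
  if (nrow(x$intervals) > 0) {
    top <- x$intervals[which.max(abs(x$intervals$peak_delta)), ]
    cat(sprintf("  top: %s:%s-%s  peak delta %.3f  pool rule: %s\n",
                top$chrom, format(top$start, big.mark = ","),
                format(top$end, big.mark = ","), top$peak_delta,
                top$supports_pool_rule))
  }
  invisible(x)
}
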