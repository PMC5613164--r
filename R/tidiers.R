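#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a SNP-index scan
#'
#' One row per sliding window with pool means, delta(SNP-index), null
#' bounds and the significance flag.
#'
#' @param x A `bsa_scan` from [scan_pool_depths()].
#' @param ... Unused.
#' @return The window tibble.
#' @method tidy bsa_scan
#' @export
tidy.bsa_scan <- function(x, ...) {
  tibble::as_tibble(x$windows)
}

#' One-line summary of a SNP-index scan
#'
#' @param x A `bsa_scan`.
#' @param ... Unused.
#' @return A one-row tibble: site and window counts, number significant,
#'   number of candidate intervals, the top interval's coordinates and
#'   peak delta, and the confidence level used.
#' @method glance bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  top <- if (nrow(x$intervals) > 0) {
    x$intervals[which.max(abs(x$intervals$peak_delta)), ]
  } else {
    tibble::tibble(chrom = NA_character_, start = NA_real_, end = NA_real_,
                   peak_delta = NA_real_)
  }
  tibble::tibble(
    n_sites = nrow(x$sites),
    n_windows = nrow(x$windows),
    n_windows_nonempty = sum(x$windows$n_sites > 0),
    n_significant = sum(x$windows$significant, na.rm = TRUE),
    n_intervals = nrow(x$intervals),
    top_chrom = top$chrom, top_start = top$start, top_end = top$end,
    top_peak_delta = top$peak_delta,
    confidence = x$params$confidence
  )
}

#' Plot a delta(SNP-index) scan
#'
#' Draws the windowed delta(SNP-index) along each chromosome with the
#' depth-matched null confidence band shaded and candidate intervals
#' highlighted.
#'
#' @param object A `bsa_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_scan
#' @export
autoplot.bsa_scan <- function(object, ...) {
  w <- object$windows[object$windows$n_sites > 0, ]
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$midpoint / 1e6)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$delta), colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(Delta * "(SNP-index)"),
                  title = "Sliding-window Δ(SNP-index) with null band") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
  if (nrow(object$intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -1, ymax = 1, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.15)
  }
  p
}

#' Plot per-pool windowed SNP-index
#'
#' Both pools' windowed mean SNP-index along the genome; near a QTL the
#' two curves separate towards the 0.7/0.3 signature.
#'
#' @param scan A `bsa_scan`.
#' @return A ggplot object.
#' @export
plot_snp_index <- function(scan) {
  w <- scan$windows[scan$windows$n_sites > 0, ] |>
    tidyr::pivot_longer(c("mean_index_L", "mean_index_H"),
                        names_to = "pool", values_to = "index") |>
    dplyr::mutate(pool = ifelse(.data$pool == "mean_index_L",
                                "low bulk", "high bulk"))
  ggplot2::ggplot(w, ggplot2::aes(.data$midpoint / 1e6, .data$index,
                                  colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "windowed SNP-index",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
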