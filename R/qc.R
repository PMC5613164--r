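#' Mapping rate from read counts
#'
#' `mapped / total * 100`, rounded half-up to two decimals, matching how
#' sequencing summary tables print it.
#'
#' @param mapped_reads,total_reads Read counts.
#' @return Percentage(s), 2 decimals.
#' @examples
#' mapping_rate(54162109, 55403332)  # 97.76
#' @export
mapping_rate <- function(mapped_reads, total_reads) {
  abort_if(any(total_reads <= 0), "total_reads must be positive")
  abort_if(any(mapped_reads > total_reads),
           "mapped_reads cannot exceed total_reads")
  abort_if(any(mapped_reads < 0), "counts must be non-negative")
  round_half_up(mapped_reads / total_reads * 100, 2)
}

#' Effective rate from base counts
#'
#' `clean_bases / raw_bases * 100`, rounded half-up to two decimals. Note:
#' published report tables sometimes print an "effective rate" computed
#' under a different, unstated definition; this function is the plain
#' clean/raw ratio.
#'
#' @param clean_bases,raw_bases Base counts (bp).
#' @return Percentage(s), 2 decimals.
#' @export
effective_rate <- function(clean_bases, raw_bases) {
  abort_if(any(raw_bases <= 0), "raw_bases must be positive")
  abort_if(any(clean_bases < 0 | clean_bases > raw_bases),
           "clean_bases must be in [0, raw_bases]")
  round_half_up(clean_bases / raw_bases * 100, 2)
}

#' Summarize a sequencing-counts table
#'
#' Adds `mapping_rate` and/or `effective_rate` columns to a per-sample
#' counts table, whichever input columns are present.
#'
#' @param data A data frame with `sample` plus `mapped_reads`/`total_reads`
#'   and/or `clean_bases`/`raw_bases`.
#' @return The table as a tibble with rate columns appended.
#' @export
summarize_sequencing <- function(data) {
  out <- tibble::as_tibble(data)
  if (all(c("mapped_reads", "total_reads") %in% names(out))) {
    out$mapping_rate <- mapping_rate(out$mapped_reads, out$total_reads)
  }
  if (all(c("clean_bases", "raw_bases") %in% names(out))) {
    out$effective_rate <- effective_rate(out$clean_bases, out$raw_bases)
  }
  out
}
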