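#' Design InDel markers inside an interval
#'
#' One PCR-scorable marker per parental InDel in the target interval whose
#' ref/alt length difference is at least `min_size_diff` bp (default 4,
#' resolvable on a gel). For each marker the 500-bp reference flanks are
#' extracted: left flank `[pos - flank_bp, pos)`, right flank
#' `(indel_end, indel_end + flank_bp]`, where `indel_end` is the last
#' reference base of the InDel. Flanks truncated at a chromosome end are
#' flagged. Markers are named `ID1`, `ID2`, ... in coordinate order.
#'
#' @param variants Variant tibble `chrom`, `pos`, `ref`, `alt`, `kind`.
#' @param interval List or one-row data frame `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param genome Named character vector or [Biostrings::DNAStringSet]
#'   covering the interval.
#' @param min_size_diff Minimum |len(ref) - len(alt)| in bp (default 4).
#' @param flank_bp Flank length (default 500).
#' @return A tibble `marker_id`, `chrom`, `pos`, `size_diff`,
#'   `left_flank`, `right_flank`, `truncated`.
#' @export
design_indel_markers <- function(variants, interval, genome,
                                 min_size_diff = 4, flank_bp = 500) {
  interval <- as.list(interval)
  chrom_len <- if (inherits(genome, "DNAStringSet")) {
    length(genome[[interval$chrom]])
  } else nchar(genome[[interval$chrom]])
  abort_if(is.null(chrom_len) || interval$start < 1 ||
             interval$end > chrom_len, "interval outside genome")
  cand <- variants |>
    dplyr::filter(.data$kind == "InDel", .data$chrom == interval$chrom,
                  .data$pos >= interval$start, .data$pos <= interval$end) |>
    dplyr::mutate(size_diff = abs(nchar(.data$ref) - nchar(.data$alt))) |>
    dplyr::filter(.data$size_diff >= min_size_diff) |>
    dplyr::arrange(.data$pos)
  if (nrow(cand) == 0) {
    return(tibble::tibble(marker_id = character(), chrom = character(),
                          pos = numeric(), size_diff = numeric(),
                          left_flank = character(), right_flank = character(),
                          truncated = logical()))
  }
  flanks <- purrr::map(seq_len(nrow(cand)), function(i) {
    pos <- cand$pos[i]
    indel_end <- pos + nchar(cand$ref[i]) - 1
    ls <- max(1, pos - flank_bp); le <- pos - 1
    rs <- indel_end + 1; re <- min(chrom_len, indel_end + flank_bp)
    left <- if (le >= ls) genome_seq(genome, interval$chrom, ls, le) else ""
    right <- if (re >= rs) genome_seq(genome, interval$chrom, rs, re) else ""
    list(left = left, right = right,
         truncated = nchar(left) < flank_bp || nchar(right) < flank_bp)
  })
  tibble::tibble(
    marker_id = sprintf("ID%d", seq_len(nrow(cand))),
    chrom = cand$chrom, pos = cand$pos, size_diff = cand$size_diff,
    left_flank = purrr::map_chr(flanks, "left"),
    right_flank = purrr::map_chr(flanks, "right"),
    truncated = purrr::map_lgl(flanks, "truncated")
  )
}

#' Narrow a QTL by substitution mapping over recombinants
#'
#' For every marker, genotype-phenotype concordance is evaluated across
#' recombinants under the chosen QTL model (`donor_low`: donor homozygote
#' implies the low phenotype class; `donor_high` mirrors it).
#' Heterozygotes follow the dominance setting: with a recessive donor
#' allele (default) `H` implies the non-donor phenotype; under
#' `"exclude"` heterozygous calls are ignored. Missing genotypes are
#' ignored per marker. The mapped interval is the maximal run of fully
#' concordant markers, extended outward to the positions of the nearest
#' flanking discordant markers — the markers whose recombination
#' breakpoints bound the QTL (clipped to the outermost markers when a run
#' reaches the end of the panel). With several equally long runs the
#' first by coordinate is kept.
#'
#' @param table Long recombinant table `id`, `marker_id`, `chrom`, `pos`,
#'   `genotype` (`R`/`H`/`D`/`NA`), `phenotype_class` (`low`/`high`), as
#'   from [simulate_recombinant_panel()].
#' @param qtl_model `"donor_low"` (default) or `"donor_high"`.
#' @param het `"recessive_donor"` (default) or `"exclude"`.
#' @return A one-row tibble `chrom`, `start`, `end`, `left_marker`,
#'   `right_marker`, `n_concordant_markers`, `supporting_recombinants`
#'   (list column of ids).
#' @export
substitution_map <- function(table, qtl_model = c("donor_low", "donor_high"),
                             het = c("recessive_donor", "exclude")) {
  qtl_model <- match.arg(qtl_model)
  het <- match.arg(het)
  stopifnot(all(c("id", "marker_id", "chrom", "pos", "genotype",
                  "phenotype_class") %in% names(table)))
  abort_if(nrow(table) == 0, "empty recombinant table")
  abort_if(length(unique(table$chrom)) != 1,
           "markers must lie on one chromosome")
  markers <- table |>
    dplyr::distinct(.data$marker_id, .data$chrom, .data$pos) |>
    dplyr::arrange(.data$pos)
  abort_if(nrow(markers) < 2, "need at least 2 markers")
  abort_if(any(duplicated(markers$marker_id)),
           "marker_id maps to more than one position")
  donor_class <- if (qtl_model == "donor_low") "low" else "high"
  other_class <- setdiff(c("low", "high"), donor_class)
  expected <- function(g) {
    dplyr::case_when(
      g == "D" ~ donor_class,
      g == "R" ~ other_class,
      g == "H" & het == "recessive_donor" ~ other_class,
      TRUE ~ NA_character_   # missing or excluded heterozygote
    )
  }
  conc <- table |>
    dplyr::mutate(expect = expected(.data$genotype)) |>
    dplyr::filter(!is.na(.data$expect)) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(concordant = all(.data$expect == .data$phenotype_class),
                     .groups = "drop")
  m <- markers |>
    dplyr::left_join(conc, by = "marker_id") |>
    dplyr::mutate(concordant = dplyr::coalesce(.data$concordant, FALSE))
  abort_if(!any(m$concordant),
           "no interval consistent with phenotypes")
  r <- rle(m$concordant)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1
  best <- which(r$values)[which.max(r$lengths[r$values])]
  i1 <- run_starts[best]; i2 <- run_ends[best]
  li <- max(i1 - 1, 1); ri <- min(i2 + 1, nrow(m))
  informative <- table |>
    dplyr::filter(.data$marker_id %in% m$marker_id[li:ri]) |>
    dplyr::distinct(.data$id) |>
    dplyr::pull(.data$id)
  tibble::tibble(
    chrom = m$chrom[1],
    start = m$pos[li], end = m$pos[ri],
    left_marker = m$marker_id[li], right_marker = m$marker_id[ri],
    n_concordant_markers = i2 - i1 + 1L,
    supporting_recombinants = list(sort(informative))
  )
}
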