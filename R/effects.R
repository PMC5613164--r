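#' Construct a gene model
#'
#' A strand-aware exon/CDS structure used for variant-effect
#' classification. The translation start (`atg_pos`) is derived from the
#' CDS: the lowest CDS coordinate on the plus strand, the highest on the
#' minus strand.
#'
#' @param gene_id Gene label.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame `start`, `end` (1-based inclusive, non-
#'   overlapping).
#' @param cds Data frame `start`, `end`; must lie within exons. May be
#'   empty for non-coding models.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"))
  exons <- dplyr::arrange(tibble::as_tibble(exons), .data$start)
  cds <- dplyr::arrange(tibble::as_tibble(cds), .data$start)
  abort_if(any(exons$end < exons$start), "malformed exon interval")
  if (nrow(exons) > 1) {
    abort_if(any(exons$start[-1] <= exons$end[-nrow(exons)]),
             "exons must be non-overlapping")
  }
  if (nrow(cds) > 0) {
    inside <- vapply(seq_len(nrow(cds)), function(i)
      any(exons$start <= cds$start[i] & exons$end >= cds$end[i]), logical(1))
    abort_if(!all(inside), "CDS segments must lie within exons")
  }
  atg <- if (nrow(cds) == 0) NA_real_
  else if (strand == "+") min(cds$start) else max(cds$end)
  cds_len <- sum(cds$end - cds$start + 1)
  if (nrow(cds) > 0 && cds_len %% 3 != 0) {
    rlang::warn(sprintf("gene %s: CDS length %d not divisible by 3; classification best-effort",
                        gene_id, cds_len))
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, atg_pos = atg),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), CDS %d bp, ATG %s\n",
              x$gene_id, x$chrom, min(x$exons$start), max(x$exons$end),
              x$strand, nrow(x$exons), sum(x$cds$end - x$cds$start + 1),
              format(x$atg_pos)))
  invisible(x)
}

genome_seq <- function(genome, chrom, start, end) {
  if (inherits(genome, "DNAStringSet")) {
    abort_if(!chrom %in% names(genome), sprintf("chromosome '%s' not in genome", chrom))
    abort_if(start < 1 || end > length(genome[[chrom]]),
             "site outside genome bounds")
    as.character(Biostrings::subseq(genome[[chrom]], start, end))
  } else {
    abort_if(!chrom %in% names(genome), sprintf("chromosome '%s' not in genome", chrom))
    abort_if(start < 1 || end > nchar(genome[[chrom]]),
             "site outside genome bounds")
    substr(genome[[chrom]], start, end)
  }
}

check_in_genome <- function(site, genome) {
  len <- if (inherits(genome, "DNAStringSet")) {
    if (site$chrom %in% names(genome)) length(genome[[site$chrom]]) else NA
  } else {
    if (site$chrom %in% names(genome)) nchar(genome[[site$chrom]]) else NA
  }
  abort_if(is.na(len) || site$pos < 1 ||
             site$pos + nchar(site$ref) - 1 > len,
           "site outside genome bounds")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return(character(0))
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}

# genomic coordinates of the CDS bases in translation order
cds_positions <- function(gene) {
  pos <- unlist(purrr::map2(gene$cds$start, gene$cds$end, seq))
  if (gene$strand == "-") rev(pos) else pos
}

coding_sequence <- function(gene, genome) {
  parts <- purrr::map2_chr(gene$cds$start, gene$cds$end,
                           function(s, e) genome_seq(genome, gene$chrom, s, e))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

in_intervals <- function(pos, iv) {
  nrow(iv) > 0 && any(iv$start <= pos & iv$end >= pos)
}

# within the first/last 2 intronic bases flanking any exon-exon gap
in_splice_region <- function(pos, gene, splice_bp = 2) {
  ex <- gene$exons
  if (nrow(ex) < 2) return(FALSE)
  int_start <- ex$end[-nrow(ex)] + 1
  int_end <- ex$start[-1] - 1
  any((pos >= int_start & pos <= pmin(int_start + splice_bp - 1, int_end)) |
        (pos <= int_end & pos >= pmax(int_end - splice_bp + 1, int_start)))
}

#' Is a site in a gene's promoter?
#'
#' The promoter is the `promoter_bp` bases immediately upstream of the
#' translation start (ATG) on the gene's strand — lower coordinates for
#' plus-strand genes, higher for minus-strand — with an inclusive boundary.
#'
#' @param pos Site position (1-based bp).
#' @param gene A [gene_model()].
#' @param promoter_bp Promoter window (default 1000).
#' @return Logical.
#' @export
promoter_overlap <- function(pos, gene, promoter_bp = 1000) {
  if (is.na(gene$atg_pos)) return(FALSE)
  d <- if (gene$strand == "+") gene$atg_pos - pos else pos - gene$atg_pos
  d >= 1 && d <= promoter_bp
}

effect_levels <- c("stop_gain", "stop_loss", "nonsynonymous", "synonymous",
                   "splicing", "frameshift", "inframe_indel", "promoter",
                   "intronic", "utr", "intergenic")
large_effects <- c("stop_gain", "stop_loss", "nonsynonymous", "splicing",
                   "frameshift")

annotation_row <- function(site, gene_id, effect, detail = "") {
  tibble::tibble(chrom = site$chrom, pos = site$pos, ref = site$ref,
                 alt = site$alt, gene_id = gene_id, effect = effect,
                 detail = detail,
                 large_effect = effect %in% large_effects)
}

#' Classify a SNP against one gene model
#'
#' Within the CDS the affected codon is translated (standard nuclear code)
#' for reference and alternate alleles on the coding strand, yielding
#' synonymous / nonsynonymous / stop gain / stop loss. Variants in the two
#' intronic bases flanking a splice junction are `splicing`; exonic
#' non-CDS positions are `utr`; other intra-gene positions `intronic`;
#' positions in the promoter window `promoter`; anything else
#' `intergenic` for this gene.
#'
#' @param site One-row data frame or list: `chrom`, `pos`, `ref`, `alt`
#'   (single bases).
#' @param gene A [gene_model()].
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @param promoter_bp Promoter window (default 1000).
#' @return A one-row annotation tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `effect`, `detail`, `large_effect`).
#' @export
classify_snp <- function(site, gene, genome, promoter_bp = 1000) {
  stopifnot(nchar(site$ref) == 1, nchar(site$alt) == 1)
  abort_if(site$chrom != gene$chrom, "site and gene on different chromosomes")
  check_in_genome(site, genome)
  pos <- site$pos
  if (in_intervals(pos, gene$cds)) {
    cpos <- cds_positions(gene)
    i <- match(pos, cpos)
    cds_seq <- coding_sequence(gene, genome)
    ref_cod_i <- (i - 1) %/% 3
    cod_start <- ref_cod_i * 3 + 1
    ref_codon <- substr(cds_seq, cod_start, cod_start + 2)
    off <- i - cod_start + 1
    alt_base <- if (gene$strand == "-") revcomp(site$alt) else site$alt
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt_base
    if (nchar(ref_codon) < 3) {
      return(annotation_row(site, gene$gene_id, "nonsynonymous",
                            "truncated terminal codon"))
    }
    aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
    aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
    eff <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gain"
    else if (aa_ref == "*") "stop_loss"
    else "nonsynonymous"
    return(annotation_row(site, gene$gene_id, eff,
                          sprintf("%s>%s (%s>%s), codon %d",
                                  ref_codon, alt_codon, aa_ref, aa_alt,
                                  ref_cod_i + 1)))
  }
  classify_noncoding(site, gene, promoter_bp)
}

classify_noncoding <- function(site, gene, promoter_bp) {
  pos <- site$pos
  if (in_splice_region(pos, gene)) {
    return(annotation_row(site, gene$gene_id, "splicing",
                          "within 2 bp of an intron boundary"))
  }
  if (in_intervals(pos, gene$exons)) {
    return(annotation_row(site, gene$gene_id, "utr"))
  }
  if (pos >= min(gene$exons$start) && pos <= max(gene$exons$end)) {
    return(annotation_row(site, gene$gene_id, "intronic"))
  }
  if (promoter_overlap(pos, gene, promoter_bp)) {
    return(annotation_row(site, gene$gene_id, "promoter",
                          sprintf("%d bp upstream of ATG",
                                  abs(gene$atg_pos - pos))))
  }
  annotation_row(site, gene$gene_id, "intergenic")
}

#' Classify an InDel against one gene model
#'
#' A CDS-overlapping InDel is a `frameshift` when the ref/alt length
#' difference is not a multiple of three; in-frame InDels are
#' re-translated to detect a created (`stop_gain`) or removed
#' (`stop_loss`) stop codon, else `inframe_indel`. Non-coding positions
#' are classified as for SNPs.
#'
#' @inheritParams classify_snp
#' @return A one-row annotation tibble.
#' @export
classify_indel <- function(site, gene, genome, promoter_bp = 1000) {
  abort_if(site$chrom != gene$chrom, "site and gene on different chromosomes")
  check_in_genome(site, genome)
  len_ref <- nchar(site$ref)
  len_alt <- nchar(site$alt)
  stopifnot(len_ref != len_alt)
  # affected genomic span (VCF left-anchored: first base is context)
  span_start <- site$pos + 1
  span_end <- site$pos + max(len_ref - 1, 1)
  touches_cds <- nrow(gene$cds) > 0 &&
    any(gene$cds$start <= span_end & gene$cds$end >= span_start)
  if (!touches_cds) return(classify_noncoding(site, gene, promoter_bp))
  shift <- abs(len_ref - len_alt) %% 3
  if (shift != 0) {
    return(annotation_row(site, gene$gene_id, "frameshift",
                          sprintf("%+d bp", len_alt - len_ref)))
  }
  eff <- tryCatch(inframe_effect(site, gene, genome),
                  error = function(e) "inframe_indel")
  annotation_row(site, gene$gene_id, eff,
                 sprintf("in-frame %+d bp", len_alt - len_ref))
}

# translate the CDS with the indel applied; compare stop content.
# Only indels whose ref span lies fully inside the CDS are re-translated
# exactly; boundary-straddling ones are reported as plain in-frame.
inframe_effect <- function(site, gene, genome) {
  cds_seq <- coding_sequence(gene, genome)
  cpos <- cds_positions(gene)
  span <- seq(site$pos, site$pos + nchar(site$ref) - 1)
  idx <- sort(match(span, cpos))
  if (anyNA(idx) || length(idx) == 0) return("inframe_indel")
  alt_seq <- if (gene$strand == "-") revcomp(site$alt) else site$alt
  lo <- min(idx); hi <- max(idx)
  mutated <- paste0(substr(cds_seq, 1, lo - 1), alt_seq,
                    substr(cds_seq, hi + 1, nchar(cds_seq)))
  aa_ref <- translate_codons(cds_seq)
  aa_alt <- translate_codons(mutated)
  ref_stop <- match("*", aa_ref)
  alt_stop <- match("*", aa_alt)
  # the original stop sits at ref_stop + shift codons after the indel;
  # any stop strictly earlier than that is newly created
  shift_codons <- (nchar(alt_seq) - nchar(site$ref)) / 3
  if (!is.na(alt_stop) && (is.na(ref_stop) ||
                           alt_stop < ref_stop + shift_codons)) {
    return("stop_gain")
  }
  if (!is.na(ref_stop) && is.na(alt_stop)) return("stop_loss")
  "inframe_indel"
}

#' Classify all variants against all overlapping gene models
#'
#' Every variant is annotated against every gene whose body or promoter
#' window it touches; variants touching no gene receive a single
#' `intergenic` record.
#'
#' @param sites Variant tibble `chrom`, `pos`, `ref`, `alt`, `kind`.
#' @param genes A list of [gene_model()] objects.
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @param promoter_bp Promoter window (default 1000).
#' @return An annotation tibble, one row per (site, overlapping gene).
#' @export
classify_variants <- function(sites, genes, genome, promoter_bp = 1000) {
  stopifnot(is.data.frame(sites))
  rows <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    site <- as.list(sites[i, ])
    hits <- purrr::keep(genes, function(g) {
      g$chrom == site$chrom &&
        ((site$pos >= min(g$exons$start) && site$pos <= max(g$exons$end)) ||
           promoter_overlap(site$pos, g, promoter_bp))
    })
    if (length(hits) == 0) {
      return(annotation_row(site, NA_character_, "intergenic"))
    }
    purrr::map_dfr(hits, function(g) {
      if (site$kind == "SNP") classify_snp(site, g, genome, promoter_bp)
      else classify_indel(site, g, genome, promoter_bp)
    })
  })
  rows
}

#' Select candidate genes from effect annotations
#'
#' A gene qualifies when it carries at least one large-effect variant
#' (stop gain/loss, nonsynonymous, splice-proximal, frameshift) or at
#' least one promoter variant. Returns per-gene tallies of every effect
#' class, sorted by gene id.
#'
#' @param annotations Output of [classify_variants()].
#' @return A tibble with `gene_id`, one count column per effect class
#'   observed, `n_large_effect`, `n_promoter`, and `candidate`.
#' @export
select_candidate_genes <- function(annotations) {
  ann <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
  if (nrow(ann) == 0) {
    return(tibble::tibble(gene_id = character(), n_large_effect = integer(),
                          n_promoter = integer(), candidate = logical()))
  }
  tallies <- ann |>
    dplyr::count(.data$gene_id, .data$effect) |>
    tidyr::pivot_wider(names_from = "effect", values_from = "n",
                       values_fill = 0L)
  ann |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_large_effect = sum(.data$large_effect),
                     n_promoter = sum(.data$effect == "promoter"),
                     .groups = "drop") |>
    dplyr::left_join(tallies, by = "gene_id") |>
    dplyr::mutate(candidate = .data$n_large_effect > 0 | .data$n_promoter > 0) |>
    dplyr::arrange(.data$gene_id)
}
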