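#' Read a pool allele-depth table
#'
#' Accepts either the package's TSV layout (`chrom`, `pos`, `ref_count_L`,
#' `alt_count_L`, `ref_count_H`, `alt_count_H`) or a VCF whose two pool
#' samples carry the `AD` FORMAT field (ref,alt read counts). Records are
#' returned sorted by (chrom, pos).
#'
#' @param path Input file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param samples For VCF input, the two pool sample names in (low, high)
#'   order; defaults to the first two samples in the file.
#' @return A tibble sorted by (chrom, pos).
#' @export
read_pool_depths <- function(path, format = c("tsv", "vcf"), samples = NULL) {
  format <- match.arg(format)
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             chrom = readr::col_character(),
                             .default = readr::col_double()))
    need <- c("chrom", "pos", "ref_count_L", "alt_count_L",
              "ref_count_H", "alt_count_H")
    missing <- setdiff(need, names(out))
    abort_if(length(missing) > 0,
             paste("missing column(s):", paste(missing, collapse = ", ")))
    bad <- which(!stats::complete.cases(out[, need]))
    abort_if(length(bad) > 0,
             paste("malformed depth record at data line(s):",
                   paste(utils::head(bad, 5), collapse = ", ")))
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    sn <- colnames(v@gt)[-1]
    samples <- samples %||% sn[1:2]
    abort_if(length(sn) < 2, "VCF must carry two pool samples")
    ad <- vcfR::extract.gt(v, element = "AD")
    abort_if(is.null(ad) || any(is.na(ad[, samples])),
             paste("missing AD field for sample(s):",
                   paste(samples[colSums(is.na(ad[, samples, drop = FALSE])) > 0],
                         collapse = ", ")))
    split_ad <- function(x) {
      parts <- strsplit(x, ",", fixed = TRUE)
      list(ref = as.integer(vapply(parts, `[`, "", 1)),
           alt = as.integer(vapply(parts, `[`, "", 2)))
    }
    lo <- split_ad(ad[, samples[1]])
    hi <- split_ad(ad[, samples[2]])
    fix <- fix_matrix(v)
    out <- tibble::tibble(chrom = fix[, "CHROM"],
                          pos = as.numeric(fix[, "POS"]),
                          ref_count_L = lo$ref, alt_count_L = lo$alt,
                          ref_count_H = hi$ref, alt_count_H = hi$alt)
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

# getFIX() drops to a named vector for single-variant files
fix_matrix <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix
}

#' Write a pool allele-depth table
#'
#' @param depths The wide L/H depth tibble.
#' @param path Output file.
#' @param format `"tsv"` (default) or `"vcf"` (two pool samples, `AD` and
#'   `DP` FORMAT fields; `ref`/`alt` columns used when present, `N`
#'   placeholders otherwise).
#' @return `path`, invisibly.
#' @export
write_pool_depths <- function(depths, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(depths, path)
    return(invisible(path))
  }
  ref <- if ("ref" %in% names(depths)) depths$ref else rep("N", nrow(depths))
  alt <- if ("alt" %in% names(depths)) depths$alt else rep("N", nrow(depths))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
                  depths$chrom, as.integer(depths$pos), ref, alt,
                  depths$ref_count_L, depths$alt_count_L,
                  depths$ref_count_L + depths$alt_count_L,
                  depths$ref_count_H, depths$alt_count_H,
                  depths$ref_count_H + depths$alt_count_H)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL_pool\tH_pool",
    body), path)
  invisible(path)
}

#' Write parental variant sites as a two-sample VCF
#'
#' Recipient parent is the reference (GT `0/0`), donor parent is
#' homozygous alternate (GT `1/1`).
#'
#' @param sites Variant tibble `chrom`, `pos`, `ref`, `alt`.
#' @param path Output file.
#' @param sample_names Two column names, recipient then donor.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(sites, path,
                               sample_names = c("recipient", "donor")) {
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t0/0\t1/1",
                  sites$chrom, as.integer(sites$pos), sites$ref, sites$alt)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(sample_names, collapse = "\t")),
    body), path)
  invisible(path)
}

#' Read parental variant sites from a VCF
#'
#' @param path VCF path (plain text or bgzipped).
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `kind`, sorted.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- fix_matrix(v)
  tibble::tibble(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                 ref = fix[, "REF"], alt = fix[, "ALT"]) |>
    dplyr::mutate(kind = ifelse(nchar(.data$ref) == 1 & nchar(.data$alt) == 1,
                                "SNP", "InDel")) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Write a window scan as TSV
#'
#' @param windows Thresholded window tibble (see [add_null_thresholds()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(windows, path) {
  readr::write_tsv(windows, path)
  invisible(path)
}

#' Write candidate intervals as BED
#'
#' Internal 1-based inclusive intervals become 0-based half-open BED rows;
#' `peak_delta` is written in the score column when present.
#'
#' @param intervals Interval tibble with `chrom`, `start`, `end`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  bed <- to_bed(intervals)
  bed$name <- sprintf("interval_%d", seq_len(nrow(bed)))
  if ("peak_delta" %in% names(intervals)) bed$score <- intervals$peak_delta
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write InDel markers as TSV plus a FASTA of flanks
#'
#' @param markers Output of [design_indel_markers()].
#' @param tsv_path Marker table output path.
#' @param fasta_path Optional FASTA path for the flank sequences
#'   (`<marker>_L` / `<marker>_R` records).
#' @return `tsv_path`, invisibly.
#' @export
write_markers <- function(markers, tsv_path, fasta_path = NULL) {
  readr::write_tsv(dplyr::select(markers, -dplyr::any_of(c("left_flank",
                                                           "right_flank"))),
                   tsv_path)
  if (!is.null(fasta_path) && nrow(markers) > 0) {
    seqs <- c(rbind(markers$left_flank, markers$right_flank))
    names(seqs) <- c(rbind(paste0(markers$marker_id, "_L"),
                           paste0(markers$marker_id, "_R")))
    seqs <- seqs[nchar(seqs) > 0]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  }
  invisible(tsv_path)
}

#' Read a recombinant genotype table
#'
#' Wide TSV: one row per recombinant with columns `id`,
#' `phenotype_class`, then one genotype column per marker named
#' `<marker_id>@<chrom>:<pos>`; values `R`, `H`, `D` or `.`/empty for
#' missing. Returned in the long layout used by [substitution_map()].
#'
#' @param path Input TSV.
#' @return A long tibble `id`, `marker_id`, `chrom`, `pos`, `genotype`,
#'   `phenotype_class`.
#' @export
read_recombinant_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  abort_if(!all(c("id", "phenotype_class") %in% names(wide)),
           "need 'id' and 'phenotype_class' columns")
  long <- wide |>
    tidyr::pivot_longer(-c("id", "phenotype_class"),
                        names_to = "marker", values_to = "genotype") |>
    tidyr::separate_wider_regex("marker",
                                c(marker_id = "[^@]+", "@",
                                  chrom = "[^:]+", ":", pos = "[0-9]+")) |>
    dplyr::mutate(pos = as.numeric(.data$pos),
                  genotype = dplyr::na_if(dplyr::na_if(.data$genotype, "."), ""))
  dplyr::select(long, "id", "marker_id", "chrom", "pos", "genotype",
                "phenotype_class")
}

#' Write a recombinant genotype table
#'
#' Inverse of [read_recombinant_table()].
#'
#' @param table Long recombinant tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_recombinant_table <- function(table, path) {
  wide <- table |>
    dplyr::mutate(marker = sprintf("%s@%s:%d", .data$marker_id, .data$chrom,
                                   as.integer(.data$pos)),
                  genotype = dplyr::coalesce(.data$genotype, ".")) |>
    dplyr::select("id", "phenotype_class", "marker", "genotype") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "genotype")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read gene models from GFF3 or a plain feature TSV
#'
#' GFF3 ingest uses rtracklayer when available; the TSV layout
#' (`gene_id`, `chrom`, `strand`, `feature` in `exon`/`CDS`, `start`,
#' `end`) needs no extra dependency and is what [write_gene_models_tsv()]
#' produces.
#'
#' @param path Input file.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @return A list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  feats <- if (format == "gff3") {
    rlang::check_installed("rtracklayer", "for GFF3 input")
    g <- rtracklayer::import(path)
    gd <- as.data.frame(g)
    gd <- gd[gd$type %in% c("exon", "CDS"), ]
    gid <- gd$gene_id %||% gd$Parent
    tibble::tibble(gene_id = sub("\\.[0-9]+$", "", as.character(gid)),
                   chrom = as.character(gd$seqnames),
                   strand = as.character(gd$strand),
                   feature = ifelse(gd$type == "CDS", "CDS", "exon"),
                   start = gd$start, end = gd$end)
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      gene_id = readr::col_character(),
                      chrom = readr::col_character(),
                      strand = readr::col_character(),
                      feature = readr::col_character(),
                      start = readr::col_double(),
                      end = readr::col_double()))
  }
  feats |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(df, key) {
      gene_model(key$gene_id, df$chrom[1], df$strand[1],
                 exons = df[df$feature == "exon", c("start", "end")],
                 cds = df[df$feature == "CDS", c("start", "end")])
    })
}

#' Write gene models as a plain feature TSV
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_gene_models_tsv <- function(genes, path) {
  rows <- purrr::map_dfr(genes, function(g) {
    dplyr::bind_rows(
      tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                     feature = "exon", start = g$exons$start, end = g$exons$end),
      tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                     feature = "CDS", start = g$cds$start, end = g$cds$end))
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Write phenotypes as TSV
#'
#' @param pheno Tibble `id`, `nue`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path)
  invisible(path)
}

#' Read phenotypes from TSV
#'
#' Accepts either pre-computed `id`, `nue` or raw measurements
#' (`id`, `tn_f`, `tn_0`, `n_applied`), which are converted with
#' [compute_nue()].
#'
#' @param path Input TSV.
#' @return A tibble with at least `id`, `nue`.
#' @export
read_phenotypes <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"nue" %in% names(out)) out <- compute_nue(out)
  out
}
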