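test_that("SNP classification covers stop gain/loss, synonymous, splicing", {
  loc <- toy_locus()
  # CDS = ATG AAA TGG TAA at 51..62
  expect_equal(classify_snp(snp_site(54, "A", "T"), loc$gene, loc$genome)$effect,
               "stop_gain")        # AAA -> TAA
  expect_equal(classify_snp(snp_site(56, "A", "G"), loc$gene, loc$genome)$effect,
               "synonymous")       # AAA -> AAG (Lys)
  expect_equal(classify_snp(snp_site(55, "A", "C"), loc$gene, loc$genome)$effect,
               "nonsynonymous")    # AAA -> ACA
  expect_equal(classify_snp(snp_site(60, "T", "C"), loc$gene, loc$genome)$effect,
               "stop_loss")        # TAA -> CAA
  expect_equal(classify_snp(snp_site(70, "G", "A"), loc$gene, loc$genome)$effect,
               "utr")
  expect_equal(classify_snp(snp_site(45, "C", "A"), loc$gene, loc$genome)$effect,
               "utr")
  expect_error(classify_snp(snp_site(9999, "G", "A"), loc$gene, loc$genome),
               "outside genome")
})

test_that("splice classification uses the 2-bp intron boundary rule", {
  g <- paste0(strrep("C", 10), "ATGAAA", strrep("G", 20), "TGGTAA",
              strrep("T", 60))
  genome <- c(chr1 = g)
  suppressWarnings(gene <- gene_model(
    "SPL", "chr1", "+",
    exons = data.frame(start = c(11, 37), end = c(16, 42)),
    cds = data.frame(start = c(11, 37), end = c(16, 42))))
  # intron is 17..36; 2-bp boundaries are 17-18 and 35-36
  for (p in c(17, 18, 35, 36)) {
    expect_equal(classify_snp(snp_site(p, "G", "A"), gene, genome)$effect,
                 "splicing")
  }
  for (p in c(19, 25, 34)) {
    expect_equal(classify_snp(snp_site(p, "G", "A"), gene, genome)$effect,
                 "intronic")
  }
})

test_that("codon classification agrees with an independent 64-entry oracle", {
  loc <- toy_locus()
  tab <- oracle_codon_table()
  bases <- c("A", "C", "G", "T")
  cds <- strsplit(loc$cds_seq, "")[[1]]
  checked <- 0L
  for (i in seq_along(cds)) {
    pos <- loc$cds_start + i - 1L
    codon_i <- (i - 1) %/% 3
    off <- i - codon_i * 3 - 1L   # 0-based offset in codon
    ref_codon <- paste(cds[(codon_i * 3 + 1):(codon_i * 3 + 3)], collapse = "")
    for (alt in setdiff(bases, cds[i])) {
      alt_codon <- ref_codon
      substr(alt_codon, off + 1, off + 1) <- alt
      aa_ref <- tab[[ref_codon]]; aa_alt <- tab[[alt_codon]]
      expected <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "stop_gain"
      else if (aa_ref == "*") "stop_loss"
      else "nonsynonymous"
      got <- classify_snp(snp_site(pos, cds[i], alt), loc$gene, loc$genome)
      expect_equal(got$effect, expected,
                   info = sprintf("pos %d %s>%s", pos, cds[i], alt))
      checked <- checked + 1L
    }
  }
  expect_equal(checked, 3L * nchar(loc$cds_seq))
})

test_that("InDel classification separates frameshift from in-frame stop changes", {
  loc <- toy_locus()
  expect_equal(classify_indel(indel_site(52, "T", "TA"), loc$gene,
                              loc$genome)$effect, "frameshift")
  expect_equal(classify_indel(indel_site(55, "AAT", "A"), loc$gene,
                              loc$genome)$effect, "frameshift")
  # 3-bp deletion of AAA codon: in-frame, stop retained
  expect_equal(classify_indel(indel_site(53, "GAAA", "G"), loc$gene,
                              loc$genome)$effect, "inframe_indel")
  # 3-bp insertion creating an in-frame TAA directly after codon 1
  expect_equal(classify_indel(indel_site(53, "G", "GTAA"), loc$gene,
                              loc$genome)$effect, "stop_gain")
  # deleting the stop codon in-frame
  expect_equal(classify_indel(indel_site(59, "GTAA", "G"), loc$gene,
                              loc$genome)$effect, "stop_loss")
})

test_that("promoter overlap is strand-aware with an inclusive 1-kb boundary", {
  plus <- gene_model("P", "chr1", "+",
                     exons = data.frame(start = 5000, end = 5600),
                     cds = data.frame(start = 5000, end = 5599))
  expect_true(promoter_overlap(4500, plus))
  expect_true(promoter_overlap(4000, plus))    # exactly 1 kb: inclusive
  expect_false(promoter_overlap(3999, plus))
  expect_false(promoter_overlap(5000, plus))   # the ATG itself is not promoter

  minus <- gene_model("M", "chr1", "-",
                      exons = data.frame(start = 4400, end = 5000),
                      cds = data.frame(start = 4401, end = 5000))
  expect_true(promoter_overlap(5400, minus))
  expect_true(promoter_overlap(6000, minus))
  expect_false(promoter_overlap(6001, minus))
  expect_false(promoter_overlap(4500, minus))
})

test_that("strand symmetry: mirrored locus yields identical effect classes", {
  loc <- toy_locus()
  L <- nchar(loc$genome[["chr1"]])
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  genome_rc <- c(chr1 = rc(loc$genome[["chr1"]]))
  flip <- function(a, b) c(L - b + 1, L - a + 1)
  ex <- flip(41, 80); cd <- flip(51, 62)
  gene_rc <- gene_model("TOY1", "chr1", "-",
                        exons = data.frame(start = ex[1], end = ex[2]),
                        cds = data.frame(start = cd[1], end = cd[2]))
  for (probe in list(snp_site(54, "A", "T"), snp_site(56, "A", "G"),
                     snp_site(55, "A", "C"), snp_site(60, "T", "C"))) {
    mirrored <- list(chrom = "chr1", pos = L - probe$pos + 1,
                     ref = rc(probe$ref), alt = rc(probe$alt), kind = "SNP")
    expect_equal(classify_snp(mirrored, gene_rc, genome_rc)$effect,
                 classify_snp(probe, loc$gene, loc$genome)$effect)
  }
})

test_that("every variant gets one annotation per overlapping gene; candidates tally", {
  loc <- toy_locus()
  # extend the toy chromosome so promoter windows do not all overlap
  genome <- c(chr1 = paste0(loc$genome[["chr1"]], strrep("A", 2800)))
  genes <- list(loc$gene,
                gene_model("TOY2", "chr1", "+",
                           exons = data.frame(start = 2120, end = 2180),
                           cds = data.frame(start = 2130, end = 2141)),
                gene_model("TOY3", "chr1", "+",
                           exons = data.frame(start = 2185, end = 2195),
                           cds = data.frame(start = 2186, end = 2194)))
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(54, 56, 2133, 2100, 25, 1000),
    ref = c("A", "A", "T", "A", "C", "A"),
    alt = c("T", "G", "TC", "G", "A", "G"),
    kind = c("SNP", "SNP", "InDel", "SNP", "SNP", "SNP"))
  ann <- classify_variants(sites, genes, genome)
  # 2100 is within 1 kb upstream of both TOY2 ATG (2130) and TOY3 ATG (2186)
  expect_equal(sum(ann$pos == 2100), 2)
  expect_setequal(ann$effect[ann$pos == 2100], "promoter")
  # CDS site annotated once, against its own gene only
  expect_equal(sum(ann$pos == 54), 1)
  expect_equal(ann$effect[ann$pos == 25], "promoter")  # 26 bp upstream of TOY1
  # a site overlapping nothing gets exactly one intergenic record
  expect_equal(ann$effect[ann$pos == 1000], "intergenic")
  expect_equal(sum(ann$pos == 1000), 1)

  cand <- select_candidate_genes(ann)
  expect_true(cand$candidate[cand$gene_id == "TOY1"])    # stop_gain at 54
  expect_true(cand$candidate[cand$gene_id == "TOY2"])    # frameshift at 2133
  # a gene with only synonymous hits is excluded
  syn_only <- classify_variants(sites[2, ], genes, genome)
  cs <- select_candidate_genes(syn_only)
  expect_false(cs$candidate[cs$gene_id == "TOY1"])
})
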