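# Shared fixtures: small configurations and toy gene models built in code.

# compact genome for fast module tests
small_config <- function(seed = 1L, ...) {
  sim_config(chrom_lengths = c(chrA = 1e6L, chrB = 1e6L),
             variant_density = 1e-3, qtl_chrom = "chrA", qtl_pos = 5e5L,
             seed = seed, ...)
}

# toy plus-strand gene: CDS "ATG AAA TGG TAA" within a 200-bp chromosome
toy_locus <- function() {
  cds_seq <- "ATGAAATGGTAA"
  g <- paste0(strrep("C", 50), cds_seq, strrep("G", 38), strrep("T", 100))
  genome <- c(chr1 = g)
  gene <- gene_model("TOY1", "chr1", "+",
                     exons = data.frame(start = 41, end = 80),
                     cds = data.frame(start = 51, end = 62))
  list(genome = genome, gene = gene, cds_start = 51, cds_seq = cds_seq)
}

# independent standard-code codon table for the translation oracle
oracle_codon_table <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  aas <- c(
    AAA = "K", AAC = "N", AAG = "K", AAT = "N", ACA = "T", ACC = "T",
    ACG = "T", ACT = "T", AGA = "R", AGC = "S", AGG = "R", AGT = "S",
    ATA = "I", ATC = "I", ATG = "M", ATT = "I", CAA = "Q", CAC = "H",
    CAG = "Q", CAT = "H", CCA = "P", CCC = "P", CCG = "P", CCT = "P",
    CGA = "R", CGC = "R", CGG = "R", CGT = "R", CTA = "L", CTC = "L",
    CTG = "L", CTT = "L", GAA = "E", GAC = "D", GAG = "E", GAT = "D",
    GCA = "A", GCC = "A", GCG = "A", GCT = "A", GGA = "G", GGC = "G",
    GGG = "G", GGT = "G", GTA = "V", GTC = "V", GTG = "V", GTT = "V",
    TAA = "*", TAC = "Y", TAG = "*", TAT = "Y", TCA = "S", TCC = "S",
    TCG = "S", TCT = "S", TGA = "*", TGC = "C", TGG = "W", TGT = "C",
    TTA = "L", TTC = "F", TTG = "L", TTT = "F")
  stopifnot(identical(sort(names(aas)), codons))
  aas
}

snp_site <- function(pos, ref, alt) {
  list(chrom = "chr1", pos = pos, ref = ref, alt = alt, kind = "SNP")
}

indel_site <- function(pos, ref, alt) {
  list(chrom = "chr1", pos = pos, ref = ref, alt = alt, kind = "InDel")
}
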