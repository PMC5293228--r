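# Shared fixture builders: everything generated in code, no stored binaries.

# The printed shared-SNP table bundled with the package (22 rows).
published_snps_path <- function()
  system.file("extdata", "published_shared_snps.tsv", package = "crosstrait")

read_published_snps <- function()
  read.table(published_snps_path(), header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)

# Small sumstats table written to a temp file; returns the path.
write_toy_sumstats <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A 5-SNP LD block with a hand-specified correlation matrix.
toy_block5 <- function() {
  corr <- matrix(c(
    1.00, 0.80, 0.50, 0.10, 0.00,
    0.80, 1.00, 0.60, 0.20, 0.05,
    0.50, 0.60, 1.00, 0.40, 0.10,
    0.10, 0.20, 0.40, 1.00, 0.70,
    0.00, 0.05, 0.10, 0.70, 1.00), 5, 5)
  snps <- data.frame(
    snp_id = paste0("s", 1:5), chrom = "1",
    pos = c(100, 200, 300, 400, 500),
    allele1 = c("A", "A", "T", "A", "T"),
    allele2 = c("G", "C", "G", "G", "C"),
    stringsAsFactors = FALSE)
  ld_block(snps, corr)
}

# One-row sumstats records for harmonize() tests.
rec <- function(id = "rs1", a1 = "A", a2 = "G", z = 1.5) {
  sumstats(snp_id = id, chrom = "1", pos = 1000,
           allele1 = a1, allele2 = a2, z = z,
           n_case = 100, n_control = 100)
}

# Index-SNP list with the mapping filter's exclusion classes:
# n_auto autosomal SNVs, n_x X-chromosomal SNVs, n_indel indels.
make_index_list <- function(n_auto, n_x, n_indel) {
  n <- n_auto + n_x + n_indel
  a1 <- rep("A", n); a2 <- rep("G", n)
  chrom <- rep("1", n)
  if (n_x > 0) chrom[n_auto + seq_len(n_x)] <- "X"
  if (n_indel > 0) a1[n_auto + n_x + seq_len(n_indel)] <- "AG"
  sumstats(snp_id = sprintf("idx%03d", seq_len(n)), chrom = chrom,
           pos = seq_len(n) * 1000, allele1 = a1, allele2 = a2,
           z = rep(2, n), n_case = 10, n_control = 10)
}

# Tiny annotation + interval layout for gene-set tests.
toy_annotation <- function() {
  data.frame(
    gene_id = paste0("g", 1:6), chrom = "1",
    start = c(1000, 50000, 120000, 200000, 300000, 400000),
    end = c(5000, 60000, 130000, 210000, 310000, 410000),
    stringsAsFactors = FALSE)
}
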