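# Shared fixtures built in code.

# deterministic 6-cell x 4-gene toy experiment
toy_experiment <- function(vehicle = "DMSO") {
  counts <- matrix(
    c(5, 0, 2, 1,
      0, 3, 0, 4,
      2, 2, 2, 2,
      9, 1, 0, 0,
      0, 1, 0, 0,
      1, 5, 3, 2),
    nrow = 6, byrow = TRUE)
  colnames(counts) <- c("MT-CO1", "ACTB", "GAPDH", "TP53")
  pooled_experiment(
    counts,
    data.frame(barcode = paste0("bc", 1:6),
               line_id = rep(c("A", "B"), length.out = 6),
               condition = rep(c(vehicle, "drug"), each = 3),
               dose = rep(c(0, 1), each = 3)))
}

# minimal VCF text: 2 sample columns, 3 biallelic SNPs, one multiallelic,
# one indel, one uncalled genotype
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tlineA\tlineB",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t./.",
    "chr1\t400\t.\tT\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t500\t.\tTA\tT\t.\tPASS\t.\tGT\t0/0\t1/1"
  ), path)
  path
}

# independent plug-in MI oracle (direct double loop over the joint table)
.mi_oracle <- function(bins, memb) {
  total <- 0
  for (b in unique(bins)) {
    for (m in c(TRUE, FALSE)) {
      pj <- mean(bins == b & memb == m)
      if (pj > 0)
        total <- total + pj * log(pj / (mean(bins == b) * mean(memb == m)))
    }
  }
  total
}

# two-line reference at opposite homozygous dosages
opposite_reference <- function(n_variants = 20) {
  genotype_reference(
    rbind(rep(0, n_variants), rep(1, n_variants)),
    line_ids = c("ref0", "alt1"),
    variant_ids = sprintf("chr1:%d:A:G", seq_len(n_variants)))
}

# 10-cell fixture with known threshold crossings: columns are
# (genes detected, total counts, mito fraction) engineered per cell
make_qc_fixture <- function() {
  n_genes <- 1500
  thr <- qc_thresholds(min_genes = 1000, min_counts = 2000,
                       max_mito_frac = 0.15)
  # per cell: detected genes, total counts, mito fraction
  spec <- data.frame(
    genes = c(900, 1500, 1500, 1200, 999, 1001, 1400, 1100, 1200, 1300),
    total = c(5000, 5000, 5000, 1900, 5000, 2000, 2100, 6000, 2500, 8000),
    mito = c(0.05, 0.16, 0.05, 0.05, 0.05, 0.05, 0.151, 0.15, 0.00, 0.149))
  flagged <- with(spec, genes < 1000 | total < 2000 | mito > 0.15)
  counts <- matrix(0L, 10, n_genes)
  colnames(counts) <- c(paste0("MT-", 1:10), paste0("G", 1:(n_genes - 10)))
  for (i in 1:10) {
    mito_counts <- round(spec$total[i] * spec$mito[i])
    rest <- spec$total[i] - mito_counts
    n_nuc <- spec$genes[i] - (mito_counts > 0) * 10
    counts[i, 1:10] <- c(rep(floor(mito_counts / 10), 9),
                         mito_counts - 9 * floor(mito_counts / 10))
    if (any(counts[i, 1:10] == 0)) n_nuc <- spec$genes[i] -
        sum(counts[i, 1:10] > 0)
    nuc <- 10 + seq_len(n_nuc)
    base <- rep(floor(rest / n_nuc), n_nuc)
    base[1] <- base[1] + rest - sum(base)
    counts[i, nuc] <- base
  }
  exp <- pooled_experiment(
    counts, data.frame(barcode = paste0("cell", 1:10)))
  list(exp = exp, thr = thr, flagged = flagged)
}
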