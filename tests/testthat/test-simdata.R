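two_line_config <- function(seed = 1L, ...) {
  sim_config(sim_lines(id = c("A", "B")),
             conditions = data.frame(condition = c("DMSO", "drug"),
                                     dose = c(0, 1), n_reps = 1L),
             n_genes = 40, n_mito_genes = 4, cells_per_sample = 1000,
             libsize_meanlog = log(500), seed = seed, ...)
}

test_that("line draws follow the multinomial law", {
  sim <- simulate_pool(two_line_config(seed = 11))
  cm <- sim$experiment$cell_meta
  # equal lines, no drug effect: per-line fraction 0.5 within 3 binomial SDs
  for (cond in c("DMSO", "drug")) {
    n <- sum(cm$condition == cond)
    f <- mean(cm$line_id[cm$condition == cond] == "A")
    expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
  }
  # chi-squared goodness of fit across repeated small sims: the p values
  # must look uniform (no systematic deviation from the multinomial law)
  p <- vapply(1:100, function(s) {
    cfg <- sim_config(sim_lines(id = c("A", "B", "C"),
                                base_weight = c(1, 2, 3)),
                      conditions = data.frame(condition = "DMSO", dose = 0,
                                              n_reps = 1L),
                      n_genes = 5, n_mito_genes = 1, cells_per_sample = 300,
                      libsize_meanlog = log(50), seed = s)
    sim <- simulate_pool(cfg)
    obs <- table(factor(sim$experiment$cell_meta$line_id,
                        levels = c("A", "B", "C")))
    stats::chisq.test(obs, p = c(1, 2, 3) / 6)$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
  expect_lte(sum(p < 0.001), 2)  # a correct generator leaves ~0.1 expected
})

test_that("survival 1 keeps representation equal across arms", {
  sim <- simulate_pool(two_line_config(seed = 4))
  W <- sim$truth$expected_fraction
  expect_equal(W[, 1], W[, 2])
})

test_that("identical seed reproduces the experiment exactly", {
  s1 <- simulate_pool(two_line_config(seed = 7, doublet_rate = 0.05,
                                      apoptotic_rate = 0.05))
  s2 <- simulate_pool(two_line_config(seed = 7, doublet_rate = 0.05,
                                      apoptotic_rate = 0.05))
  expect_identical(as.matrix(s1$experiment$counts),
                   as.matrix(s2$experiment$counts))
  expect_identical(s1$hash_counts, s2$hash_counts)
  expect_identical(s1$truth$cells, s2$truth$cells)
})

test_that("planted log2 shifts are recovered by naive mean-log comparison", {
  # pilot run fixes the expression profile; program genes chosen among
  # well-expressed ones, then the same seed replants the shift
  base_cfg <- function(programs = list()) {
    sim_config(sim_lines(id = c("A", "B")),
               conditions = data.frame(condition = c("DMSO", "drug"),
                                       dose = c(0, 1), n_reps = 1L),
               programs = programs,
               n_genes = 1000, n_mito_genes = 10, cells_per_sample = 5000,
               libsize_meanlog = log(2000), seed = 42)
  }
  pilot <- simulate_pool(base_cfg())
  ctrl <- pilot$experiment$cell_meta$condition == "DMSO"
  rel <- Matrix::colMeans(pilot$experiment$counts[ctrl, ] /
                            Matrix::rowSums(pilot$experiment$counts[ctrl, ]))
  # mid-expression genes: well measured but a small compositional share
  genes <- names(sort(rel, decreasing = TRUE))[101:130]
  sim <- simulate_pool(base_cfg(list(list(name = "up", genes = genes,
                                          log2_shift = 1,
                                          lines = c("A", "B")))))
  cm <- sim$experiment$cell_meta
  norm <- sim$experiment$counts / Matrix::rowSums(sim$experiment$counts)
  m_t <- Matrix::colMeans(norm[cm$condition == "drug", genes])
  m_c <- Matrix::colMeans(norm[cm$condition == "DMSO", genes])
  recovered <- mean(log2(m_t / m_c))
  expect_lt(abs(recovered - 1), 0.1)
})

test_that("allele count simulation matches its sampling model", {
  ref <- opposite_reference(30)
  cells <- data.frame(barcode = paste0("c", 1:50), line = "alt1",
                      partner_line = NA, doublet = FALSE,
                      stringsAsFactors = FALSE)
  ac <- simulate_allele_counts(cells, ref, mean_depth = 30, err = 0,
                               seed = 2)
  expect_true(all(ac$ref_reads == 0))  # hom alt, no error: all reads alt
  expect_gt(nrow(ac), 0)

  empty <- simulate_allele_counts(cells, ref, mean_depth = 0, seed = 2)
  expect_equal(nrow(empty), 0)

  doub <- data.frame(barcode = paste0("d", 1:200), line = "ref0",
                     partner_line = "alt1", doublet = TRUE,
                     stringsAsFactors = FALSE)
  ad <- simulate_allele_counts(doub, ref, mean_depth = 40, err = 0,
                               seed = 3)
  frac <- sum(ad$alt_reads) / sum(ad$alt_reads + ad$ref_reads)
  expect_lt(abs(frac - 0.5), 0.02)

  bad <- data.frame(barcode = "x", line = "missing", partner_line = NA,
                    doublet = FALSE)
  expect_error(simulate_allele_counts(bad, ref), "missing from reference")
})

test_that("guide screen plants effects at the stated fold changes", {
  scr0 <- simulate_guide_screen(n_genes = 60, guides_per_gene = 4,
                                reps = 2, libsize = 5e5, seed = 5)
  cnt <- as.matrix(scr0$guides[, scr0$design$sample])
  norm <- sweep(cnt, 2, colSums(cnt), "/")
  ratio <- rowMeans(norm[, 3:4]) / rowMeans(norm[, 1:2])
  expect_lt(abs(median(ratio) - 1), 0.05)

  scr <- simulate_guide_screen(n_genes = 60, guides_per_gene = 4,
                               effects = c(GENE1 = -2), reps = 2,
                               libsize = 5e5, seed = 5)
  cnt <- as.matrix(scr$guides[, scr$design$sample])
  norm <- sweep(cnt, 2, colSums(cnt), "/")
  g1 <- scr$guides$gene == "GENE1"
  dep <- mean(rowMeans(norm[g1, 3:4]) / rowMeans(norm[g1, 1:2]))
  expect_lt(abs(log2(dep) - (-2)), 0.4)

  scr_b <- simulate_guide_screen(n_genes = 60, guides_per_gene = 4,
                                 effects = c(GENE1 = -2), reps = 2,
                                 libsize = 5e5, seed = 5)
  expect_identical(scr$guides, scr_b$guides)
})
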