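# small deterministic experiment with two lines, two arms
de_experiment <- function(seed = 1, shift_genes = NULL, shift = 0,
                          n_cells = 120, n_genes = 60) {
  set.seed(seed)
  symbols <- paste0("G", seq_len(n_genes))
  mu <- rep(30, n_genes)
  cm <- data.frame(barcode = paste0("c", seq_len(4 * n_cells)),
                   line_id = rep(c("L1", "L2"), each = 2 * n_cells),
                   condition = rep(c("DMSO", "drug", "DMSO", "drug"),
                                   each = n_cells),
                   dose = rep(c(0, 1, 0, 1), each = n_cells),
                   stringsAsFactors = FALSE)
  counts <- t(vapply(seq_len(nrow(cm)), function(i) {
    m <- mu
    if (cm$condition[i] == "drug" && !is.null(shift_genes))
      m[shift_genes] <- m[shift_genes] * 2^shift
    rpois(n_genes, m)
  }, numeric(n_genes)))
  colnames(counts) <- symbols
  pooled_experiment(counts, cm)
}

test_that("identical arms give near-zero fold changes and null p values", {
  exp <- de_experiment(seed = 2)
  fc <- per_line_log2fc(exp, "L1", "drug", "DMSO")
  expect_lt(max(abs(fc$log2fc)), 0.2)
  expect_gt(mean(fc$p_value > 0.05), 0.9)
})

test_that("a planted shift is recovered at the stated accuracy", {
  exp <- de_experiment(seed = 3, shift_genes = 1:10, shift = 1,
                       n_cells = 1000, n_genes = 40)
  fc <- per_line_log2fc(exp, "L1", "drug", "DMSO")
  planted <- fc$log2fc[1:10]
  # CP10k renormalization dilutes the planted shift by the shifted share
  dilution <- log2(1 + 10 / 40)
  expect_lt(max(abs(planted - (1 - dilution))), 0.15)
  expect_true(all(fc$p_value[1:10] < 1e-6))
})

test_that("a gene absent in both arms is a pseudocount identity", {
  exp <- de_experiment(seed = 4)
  counts <- as.matrix(exp$counts)
  counts[, 1] <- 0
  exp0 <- pooled_experiment(counts, exp$cell_meta)
  fc <- per_line_log2fc(exp0, "L1", "drug", "DMSO")
  expect_equal(fc$log2fc[1], 0)
  expect_equal(fc$p_value[1], 1)
})

test_that("too few cells raises and log2fc_matrix skips with a warning", {
  exp <- de_experiment(seed = 5, n_cells = 30)
  # thin L2's drug arm below the floor; L1 stays complete
  drop <- which(exp$cell_meta$line_id == "L2" &
                  exp$cell_meta$condition == "drug")[-(1:5)]
  exp <- subset_cells(exp, setdiff(seq_len(nrow(exp$counts)), drop))
  expect_error(per_line_log2fc(exp, "L2", "drug", "DMSO"), "fewer than")
  expect_warning(fc <- log2fc_matrix(exp, "drug", "DMSO", min_cells = 15),
                 "skipping")
  expect_equal(colnames(fc), "L1")
  expect_error(suppressWarnings(
    log2fc_matrix(exp, "drug", "DMSO", min_cells = 1e6)), "no line")
})

test_that("cross-model aggregation normalizes, is order invariant and signed", {
  set.seed(6)
  fc <- matrix(rnorm(500 * 4, 0, 0.5), 500, 4,
               dimnames = list(paste0("G", 1:500), paste0("L", 1:4)))
  fc[1:20, ] <- fc[1:20, ] - 1   # uniform down-shift
  agg <- cross_model_aggregate(fc, B = 5000, seed = 3)
  z <- attr(agg, "line_z")
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  expect_true(all(agg$mean_dz[1:20] < 0))
  # a fully unshifted matrix is centered at 0
  null_agg <- cross_model_aggregate(
    matrix(rnorm(500 * 4, 0, 0.5), 500, 4,
           dimnames = dimnames(fc)), B = 2000, seed = 4)
  expect_lt(abs(median(null_agg$mean_dz)), 0.05)

  perm <- cross_model_aggregate(fc[, c(3, 1, 4, 2)], B = 5000, seed = 3)
  expect_equal(perm$mean_dz, agg$mean_dz)
  expect_error(cross_model_aggregate(fc[, 1, drop = FALSE]), "single line")

  # BH q monotone nondecreasing in p
  o <- order(agg$p_value)
  expect_true(all(diff(agg$q_value[o]) >= -1e-15))
})

test_that("group deltas match the closed-form Welch t on a 3-gene toy", {
  fc <- rbind(G1 = c(1.0, 1.2, 0.9, 0.2, 0.1),
              G2 = c(0.0, 0.1, -0.1, 0.0, 0.1),
              G3 = c(-1, -0.8, -1.1, -0.2, -0.3))
  colnames(fc) <- paste0("L", 1:5)
  gd <- group_delta(fc, paste0("L", 1:3), paste0("L", 4:5))
  for (g in 1:3) {
    x <- fc[g, 1:3]
    y <- fc[g, 4:5]
    ht <- t.test(x, y)
    expect_equal(gd$delta[g], mean(x) - mean(y))
    expect_equal(gd$p_value[g], ht$p.value, tolerance = 1e-12)
  }
  same <- group_delta(fc, c("L1", "L2"), c("L1", "L2"))
  expect_equal(same$delta, rep(0, 3))
})

test_that("geneset shift tests detect planted shifts and self-compare to 1", {
  set.seed(9)
  stat <- stats::setNames(rnorm(2000), paste0("G", 1:2000))
  stat[1:50] <- stat[1:50] - 1
  r <- geneset_shift_test(stat, paste0("G", 1:50))
  expect_lt(r$p_mw, 1e-4)
  expect_lt(r$p_t, 1e-4)
  expect_equal(r$direction, -1)
  self <- geneset_shift_test(stat, names(stat), background = names(stat))
  expect_equal(self$p_mw, 1)
  expect_error(geneset_shift_test(stat, "NOPE"), "disjoint")
})

test_that("geneset shift p values are calibrated under random sets", {
  set.seed(10)
  stat <- stats::setNames(rnorm(500), paste0("G", 1:500))
  p <- vapply(1:200, function(i)
    geneset_shift_test(stat, sample(names(stat), 40))$p_mw, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("downsampling at k = n reproduces the full analysis in one draw", {
  set.seed(11)
  fc <- matrix(rnorm(300 * 4, 0, 0.5), 300, 4,
               dimnames = list(paste0("G", 1:300), paste0("L", 1:4)))
  fc[1:25, ] <- fc[1:25, ] - 0.8
  dm <- downsample_models(fc, ks = 4, genesets = list(s = paste0("G", 1:25)),
                          n_draws = 5, n_random = 3, B = 2000, seed = 2)
  tgt <- dm[dm$type == "target", ]
  expect_equal(nrow(tgt), 1L)
  agg <- cross_model_aggregate(fc, B = 2000, seed = 99)
  full_p <- geneset_shift_test(stats::setNames(agg$mean_dz, agg$gene),
                               paste0("G", 1:25))$p_mw
  # the shift statistic is the bootstrap-independent mean z, so the k = n
  # draw reproduces the full-analysis p exactly
  expect_equal(tgt$median_p, full_p, tolerance = 1e-12)
  expect_error(downsample_models(fc, ks = 1, genesets = list()), "out of range")
})
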