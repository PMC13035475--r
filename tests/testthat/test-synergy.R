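test_that("bliss expectation follows the independence identities", {
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0, 0.37), 0.37)
  expect_equal(bliss_expected(1, 0.2), 1)
  expect_equal(bliss_expected(0.3, 0.8), bliss_expected(0.8, 0.3))
  expect_error(bliss_expected(1.2, 0), "\\[0, 1\\]")
})

test_that("survival Bliss recovers the A-equals-AB algebraic identity", {
  # A alone = AB: synergy = -eB * (1 - eA) exactly
  ctrl <- rep(1000, 4)
  a <- rep(400, 4)    # eA = 0.6
  b <- rep(700, 4)    # eB = 0.3
  r <- bliss_from_survival(ctrl, a, b, ab = a)
  expect_equal(r$synergy, -0.3 * (1 - 0.6), tolerance = 1e-12)
  expect_error(bliss_from_survival(rep(0, 3), a, b, a), "positive")
})

test_that("independent kill yields centered synergy; planted synergy is detected", {
  set.seed(31)
  null_syn <- replicate(200, {
    n <- 1000
    x <- list(ctrl = rbinom(4, n, 0.995), a = rbinom(4, n, 0.6),
              b = rbinom(4, n, 0.5), ab = rbinom(4, n, 0.3))
    bliss_from_survival(x$ctrl, x$a, x$b, x$ab)$synergy
  })
  expect_lte(abs(median(null_syn)), 0.02)

  det <- replicate(100, {
    n <- 1000
    x <- list(ctrl = rbinom(4, n, 0.995), a = rbinom(4, n, 0.6),
              b = rbinom(4, n, 0.5), ab = rbinom(4, n, 0.15))
    bliss_from_survival(x$ctrl, x$a, x$b, x$ab)$p_value < 0.05
  })
  expect_gte(mean(det), 0.9)
})

test_that("phenotype Bliss reproduces the worked arithmetic and directions", {
  r <- phenotype_bliss(0.4, 0.6, 0.6, 0.9)
  expect_equal(r$e_a, 1 / 3, tolerance = 1e-12)
  expect_equal(r$expected, 5 / 9, tolerance = 1e-12)
  expect_equal(r$synergy, 5 / 18, tolerance = 1e-12)

  # combination at exactly the independence prediction -> 0
  e <- bliss_expected(1 / 3, 1 / 3)
  g1_ab <- 0.4 + e * 0.6
  expect_equal(phenotype_bliss(0.4, 0.6, 0.6, g1_ab)$synergy, 0,
               tolerance = 1e-12)
  # rescue: combination arrest below the singles -> negative synergy
  expect_lt(phenotype_bliss(0.4, 0.6, 0.6, 0.45)$synergy, 0)
  expect_error(phenotype_bliss(1, 0.6, 0.6, 0.9), "undefined")
})

test_that("pseudobulk sums cells per line-condition-replicate", {
  exp <- toy_experiment()
  exp$cell_meta$replicate <- "r1"
  pb <- pseudobulk(exp, min_cells = 1)
  expect_equal(sort(pb$samples$sample),
               sort(c("A_DMSO_r1", "B_DMSO_r1", "A_drug_r1", "B_drug_r1")))
  a_dmso <- which(exp$cell_meta$line_id == "A" &
                    exp$cell_meta$condition == "DMSO")
  expect_equal(pb$counts[, "A_DMSO_r1"],
               Matrix::colSums(exp$counts[a_dmso, , drop = FALSE]))
})

test_that("treatment model recovers planted effects and honors offsets", {
  sim <- simulate_synergy_pseudobulk(n_genes = 600, n_lines = 1, reps = 3,
                                     lfc_sd = 0, interaction_genes = 0,
                                     dispersion = 0.02, seed = 41)
  counts <- sim$counts
  cond <- sim$samples$condition
  # plant a clean 2-fold increase under A for 50 genes
  aj <- cond == "A"
  counts[1:50, aj] <- matrix(
    rnbinom(50 * sum(aj), mu = 2 * rowMeans(counts[1:50, cond == "vehicle"]),
            size = 1 / 0.02), 50, sum(aj))
  fit <- fit_treatment_model(counts, cond, reference = "vehicle")
  expect_lt(abs(mean(fit$beta[1:50, "A"]) - log(2)), 0.1 * log(2))
  expect_lt(abs(median(fit$beta[51:600, "A"])), 0.05)

  # doubling every count of one sample is absorbed by its size factor; the
  # geometric-mean reference spreads a factor 2^(1/n) over the cohort, so
  # treatment contrasts are recovered up to dispersion-estimation noise
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 2
  fit2 <- fit_treatment_model(counts2, cond, reference = "vehicle")
  expect_lt(median(abs(fit2$beta - fit$beta)), 0.01)
  expect_lt(max(abs(fit2$beta - fit$beta)), 0.15)
  expect_gt(stats::cor(fit2$beta[, "A"], fit$beta[, "A"]), 0.99)
  n <- ncol(counts)
  expect_equal(fit2$size_factors[[1]] / fit$size_factors[[1]],
               2^(1 - 1 / n), tolerance = 1e-6)
  expect_error(fit_treatment_model(counts, rep("one", ncol(counts))),
               ">= 2 conditions")
})

test_that("treatment coefficients agree with an independent NB GLM fit", {
  skip_if_not_installed("MASS")
  sim <- simulate_synergy_pseudobulk(n_genes = 40, n_lines = 1, reps = 4,
                                     lfc_sd = 0.5, interaction_genes = 0,
                                     dispersion = 0.05, seed = 43)
  fit <- fit_treatment_model(sim$counts, sim$samples$condition,
                             reference = "vehicle")
  cond <- factor(sim$samples$condition,
                 levels = c("vehicle", "A", "B", "AB"))
  off <- log(fit$size_factors)
  for (g in c(1, 7, 20)) {
    y <- sim$counts[g, ]
    ml <- suppressWarnings(stats::glm(
      y ~ cond + offset(off),
      family = MASS::negative.binomial(theta = 1 / fit$dispersion[g])))
    expect_equal(unname(fit$beta[g, "A"]), unname(coef(ml)[["condA"]]),
                 tolerance = 0.01)
    expect_equal(unname(fit$beta[g, "AB"]), unname(coef(ml)[["condAB"]]),
                 tolerance = 0.01)
  }
})

test_that("synergy covariates equal their definition and flag planted genes", {
  sim <- simulate_synergy_pseudobulk(n_genes = 800, n_lines = 2, reps = 2,
                                     interaction_genes = 30,
                                     interaction_lfc = -1.5, seed = 45)
  single <- dual <- list()
  for (l in unique(sim$samples$line)) {
    li <- sim$samples$line == l
    js <- li & sim$samples$condition != "AB"
    single[[l]] <- fit_treatment_model(sim$counts[, js],
                                       sim$samples$condition[js],
                                       reference = "vehicle")
    dual[[l]] <- fit_treatment_model(sim$counts[, li],
                                     sim$samples$condition[li],
                                     reference = "vehicle")
  }
  sf <- synergy_covariates(single, dual, B = 5000, seed = 2)
  S <- attr(sf, "s_by_line")
  l1 <- names(single)[1]
  manual <- (single[[l1]]$beta[, "A"] + single[[l1]]$beta[, "B"]) -
    dual[[l1]]$beta[, "AB"]
  expect_equal(unname(S[, l1]), unname(manual), tolerance = 1e-12)

  planted <- sim$truth$gene[sim$truth$interaction]
  # negative interaction -> positive covariate -> extreme top ranks
  expect_gt(mean(sf$rank[sf$gene %in% planted] > 0.95 * nrow(sf)), 0.85)
  expect_lt(abs(median(sf$z[!sf$gene %in% planted])), 0.15)
})
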