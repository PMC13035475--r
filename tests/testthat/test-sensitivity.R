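# cell_meta builder with exact per-line cell counts
meta_from_counts <- function(counts_by_line, condition, dose,
                             replicate = "r1") {
  do.call(rbind, lapply(names(counts_by_line), function(l) {
    n <- counts_by_line[[l]]
    if (n == 0) return(NULL)
    data.frame(barcode = sprintf("%s_%s_%s_%d", condition, replicate, l,
                                 seq_len(n)),
               line_id = l, condition = condition, dose = dose,
               replicate = replicate, stringsAsFactors = FALSE)
  }))
}

test_that("growth rate matches its closed form and inverts exactly", {
  expect_equal(growth_rate(100, 100, 24), 0)
  # 50,000 seeded, doubled after 72 h
  r <- growth_rate(50000, 100000, 72)
  expect_equal(r, log(2) / 72)
  expect_equal(exp(r * 72) * 50000, 100000)
  expect_error(growth_rate(0, 10, 1), "positive")
})

test_that("seed balancing is exact under both modes", {
  eq <- balance_seeding(c(a = 0.01, b = 0.01, c = 0.01), 900)
  expect_equal(unname(eq), rep(300L, 3))

  r <- c(fast = log(2) / 24, slow = log(2) / 48)
  seeds <- balance_seeding(r, 1e6, horizon = 72)
  oracle <- exp(-r * 72) / sum(exp(-r * 72)) * 1e6
  expect_equal(as.numeric(seeds), as.numeric(round(oracle)))
  expect_equal(seeds[["slow"]] / seeds[["fast"]], 2^1.5, tolerance = 1e-4)
  expect_equal(sum(seeds), 1e6)

  lit <- balance_seeding(c(a = 0.02, b = 0.01), 300, mode = "literal")
  expect_equal(unname(lit), c(100L, 200L))
  expect_error(balance_seeding(c(a = -0.1, b = 0.2), 10, mode = "literal"),
               "requires")
})

test_that("representation ratios and fractions match an independent tally", {
  cm <- rbind(meta_from_counts(list(A = 60, B = 30, C = 10), "DMSO", 0),
              meta_from_counts(list(A = 30, B = 30, C = 0), "drug", 1))
  tab <- relative_representation(cm, vehicle = "DMSO")

  # pool fractions sum to 1 per sample
  sums <- tapply(tab$pool_fraction,
                 paste(tab$condition, tab$dose, tab$replicate), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # brute-force recomputation from the raw table
  drug <- tab[tab$condition == "drug", ]
  expect_equal(drug$n_cells[drug$line == "A"], 30L)
  # zero count -> pseudocount 0.5
  fC <- 0.5 / (30 + 30 + 0.5)
  expect_equal(drug$pool_fraction[drug$line == "C"], fC)
  expect_equal(drug$ratio_vs_vehicle[drug$line == "C"], fC / 0.1)
  # display value: counts over max within condition
  expect_equal(drug$relative_representation,
               c(30, 30, 0) / 30)

  # identical counts in both arms -> ratio 1 everywhere
  cm2 <- rbind(meta_from_counts(list(A = 50, B = 25), "DMSO", 0),
               meta_from_counts(list(A = 50, B = 25), "drug", 1))
  t2 <- relative_representation(cm2)
  expect_true(all(abs(t2$ratio_vs_vehicle - 1) < 1e-12))
  expect_error(relative_representation(cm2, vehicle = "water"), "absent")
})

test_that("relative survival is a log2 depletion score, antisymmetric in arms", {
  cm <- rbind(meta_from_counts(list(A = 400, B = 400), "DMSO", 0),
              meta_from_counts(list(A = 100, B = 400), "drug", 1))
  rs <- relative_survival(cm, "drug")
  # A drops 4x relative to pool: fraction 0.5 -> 0.2; log2(0.2/0.5)
  expect_equal(rs$lines$score[rs$lines$line == "A"], log2(0.2 / 0.5))

  # no depletion -> 0
  cm0 <- rbind(meta_from_counts(list(A = 200, B = 100), "DMSO", 0),
               meta_from_counts(list(A = 200, B = 100), "drug", 1))
  expect_true(all(abs(relative_survival(cm0, "drug")$lines$score) < 1e-12))

  # swapping arms flips the sign
  fwd <- relative_survival(cm, "drug", vehicle = "DMSO")$lines$score
  cm_sw <- cm
  cm_sw$condition <- ifelse(cm$condition == "drug", "DMSO", "drug")
  cm_sw$dose <- ifelse(cm_sw$condition == "DMSO", 0, 1)
  rev <- relative_survival(cm_sw, "drug", vehicle = "DMSO")$lines$score
  expect_equal(fwd, -rev)

  g <- relative_survival(cm, "drug", groups = list(mut = c("A")))
  expect_equal(g$groups$score, fwd[1])
  expect_error(relative_survival(cm, "drug", groups = list(x = "Z")),
               "no member")
})

test_that("dose slopes match deterministic constructions", {
  # representation ratio halves per 10-fold dose -> slope log10(0.5)
  cm <- rbind(meta_from_counts(list(A = 500, B = 500), "DMSO", 0),
              meta_from_counts(list(A = 500, B = 500), "drug", 0.1),
              meta_from_counts(list(A = 250, B = 750), "drug", 1),
              meta_from_counts(list(A = 125, B = 875), "drug", 10))
  ds <- dose_slope(cm)
  a <- ds[ds$line == "A", ]
  expect_equal(a$slope, log10(0.5), tolerance = 1e-12)
  expect_lt(a$p_value, 0.2)  # one-sided, 3 points

  b <- ds[ds$line == "B", ]
  expect_gt(b$slope, 0)  # B enriches as A depletes

  # flat representation: slope 0, one-sided p around 0.5
  cm_flat <- rbind(meta_from_counts(list(A = 300, B = 300), "DMSO", 0),
                   meta_from_counts(list(A = 300, B = 300), "drug", 0.1),
                   meta_from_counts(list(A = 300, B = 300), "drug", 1),
                   meta_from_counts(list(A = 300, B = 300), "drug", 10))
  flat <- dose_slope(cm_flat)
  expect_equal(flat$slope, c(0, 0))
  expect_equal(flat$p_value, c(0.5, 0.5), tolerance = 0.2)
})

test_that("the mutation lasso selects a perfectly tracking covariate", {
  set.seed(14)
  lines <- paste0("L", 1:11)
  mm <- matrix(rbinom(11 * 6, 1, 0.4), 11, 6,
               dimnames = list(lines, paste0("MUT", 1:6)))
  mm[, 1] <- c(rep(1, 5), rep(0, 6))   # driver mutation in 5 lines
  mm <- mutation_matrix(mm)
  scores <- stats::setNames(-3 * mm[, 1] + rnorm(11, 0, 0.2), lines)
  sel <- mutation_lasso(mm, scores)
  expect_true("MUT1" %in% sel$mutation)
  expect_lt(sel$coefficient[sel$mutation == "MUT1"], 0)

  expect_warning(
    none <- mutation_lasso(mm, stats::setNames(rep(1, 11), lines)),
    "constant")
  expect_equal(nrow(none), 0)

  # deterministic given identical inputs
  sel2 <- mutation_lasso(mm, scores)
  expect_identical(sel, sel2)
})
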