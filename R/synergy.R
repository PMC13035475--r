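# Bliss-independence synergy on survival and on G1-arrest phenotypes, and
# gene-level synergy covariates: the contrast (betaA + betaB) - betaAB
# between single-agent and dual-agent treatment coefficients of a
# negative-binomial pseudobulk model.

#' Bliss-independence expected effect
#'
#' `eA + eB - eA * eB` for inhibition-scale effects in `[0, 1]`; the null
#' combined effect of two independently acting drugs.
#'
#' @param e_a,e_b Single-agent effects in `[0, 1]`.
#' @return Expected combined effect.
#' @export
bliss_expected <- function(e_a, e_b) {
  if (any(e_a < 0 | e_a > 1) || any(e_b < 0 | e_b > 1))
    stop("effects must be in [0, 1]")
  e_a + e_b - e_a * e_b
}

#' Bliss synergy from replicate survival readings
#'
#' Effects are `1 - survival / mean(control survival)`, clamped to
#' `[0, 1]`; synergy is the observed combination effect minus the Bliss
#' expectation (positive = synergy). The p value is a two-tailed two-sample
#' t test of the per-replicate combination deviation from expectation
#' against the no-drug replicates' deviation from 1 (the plate's noise
#' null); it needs >= 3 replicates in those two arms.
#'
#' @param control,a,b,ab Numeric replicate vectors of survival readings
#'   (e.g. luminescence) for vehicle, drug A, drug B and the combination.
#' @return Object of class `bliss_result`: list with `e_a`, `e_b`, `e_ab`,
#'   `expected`, `synergy`, `p_value`, `n_reps`.
#' @export
bliss_from_survival <- function(control, a, b, ab) {
  ctrl_mean <- mean(control)
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0)
    stop("control survival must be positive")
  eff <- function(x) pmin(pmax(1 - x / ctrl_mean, 0), 1)
  e_a <- mean(eff(a))
  e_b <- mean(eff(b))
  e_ab <- mean(eff(ab))
  expected <- bliss_expected(e_a, e_b)
  synergy <- e_ab - expected
  p <- NA_real_
  if (length(ab) >= 3L && length(control) >= 3L) {
    dev_ab <- eff(ab) - expected
    dev_ctrl <- eff(control) - 0
    p <- tryCatch(stats::t.test(dev_ab, dev_ctrl)$p.value,
                  error = function(e) NA_real_)
  }
  structure(list(e_a = e_a, e_b = e_b, e_ab = e_ab, expected = expected,
                 synergy = synergy, p_value = p,
                 n_reps = c(control = length(control), a = length(a),
                            b = length(b), ab = length(ab))),
            class = "bliss_result")
}

#' @export
print.bliss_result <- function(x, ...) {
  cat(sprintf(
    "bliss_result: eA = %.3f, eB = %.3f, eAB = %.3f, expected = %.3f, synergy = %+.3f (p = %s)\n",
    x$e_a, x$e_b, x$e_ab, x$expected, x$synergy, format.pval(x$p_value)))
  invisible(x)
}

#' Bliss synergy on G1-arrest phenotypes
#'
#' Treats dose-induced G1 arrest as the drug effect: per condition the
#' arrest effect is `max(0, (G1_cond - G1_vehicle) / (1 - G1_vehicle))`
#' (the fraction of the remaining non-G1 pool arrested; set
#' `normalize = FALSE` for the raw difference instead), and Bliss synergy
#' is computed on those effects. Negative synergy marks a combination that
#' rescues arrest (e.g. an ETC inhibitor co-dosed with a cytostatic).
#'
#' @param g1_vehicle,g1_a,g1_b,g1_ab G1 fractions of the line under
#'   vehicle, each single agent, and the combination.
#' @param normalize Normalize effects by `1 - G1_vehicle` (default).
#' @return List: `e_a`, `e_b`, `e_ab`, `expected`, `synergy`.
#' @export
phenotype_bliss <- function(g1_vehicle, g1_a, g1_b, g1_ab,
                            normalize = TRUE) {
  if (g1_vehicle >= 1) stop("G1 fraction of 1 under vehicle: effect undefined")
  eff <- function(g1) {
    d <- g1 - g1_vehicle
    if (normalize) d <- d / (1 - g1_vehicle)
    min(max(d, 0), 1)
  }
  e_a <- eff(g1_a)
  e_b <- eff(g1_b)
  e_ab <- eff(g1_ab)
  expected <- bliss_expected(e_a, e_b)
  list(e_a = e_a, e_b = e_b, e_ab = e_ab, expected = expected,
       synergy = e_ab - expected)
}

#' Aggregate a pooled experiment to pseudobulk
#'
#' Sums counts over cells within line x condition x replicate, the input
#' unit of the bulk-style count models.
#'
#' @param exp A [pooled_experiment()].
#' @param min_cells Minimum cells per pseudobulk sample; smaller groups
#'   are dropped with a warning.
#' @return List: `counts` (genes x samples), `samples` (`sample`, `line`,
#'   `condition`, `replicate`, `n_cells`).
#' @export
pseudobulk <- function(exp, min_cells = 10L) {
  stopifnot(inherits(exp, "pooled_experiment"))
  cm <- exp$cell_meta
  keep <- !(cm$line_id %in% c("unassigned", "doublet"))
  key <- paste(cm$line_id, cm$condition, cm$replicate, sep = "||")
  key[!keep] <- NA
  groups <- sort(unique(stats::na.omit(key)))
  M <- Matrix::sparseMatrix(
    i = match(key[keep], groups), j = which(keep), x = 1,
    dims = c(length(groups), nrow(cm)))
  counts <- as.matrix(M %*% exp$counts)
  info <- do.call(rbind, strsplit(groups, "||", fixed = TRUE))
  samples <- data.frame(sample = gsub("||", "_", groups, fixed = TRUE),
                        line = info[, 1L], condition = info[, 2L],
                        replicate = info[, 3L],
                        n_cells = as.integer(Matrix::rowSums(M)),
                        stringsAsFactors = FALSE)
  small <- samples$n_cells < min_cells
  if (any(small)) {
    warning(sum(small), " pseudobulk sample(s) below ", min_cells,
            " cells dropped")
    counts <- counts[!small, , drop = FALSE]
    samples <- samples[!small, , drop = FALSE]
  }
  out <- t(counts)
  colnames(out) <- samples$sample
  rownames(out) <- exp$gene_meta$symbol
  list(counts = out, samples = samples)
}

# median-of-ratios size factors (geometric-mean reference)
.size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg)
  ok <- is.finite(ref)
  if (sum(ok) < 10L) stop("too few all-positive genes for size factors")
  sf <- apply(lg[ok, , drop = FALSE], 2L, function(col)
    exp(stats::median(col - ref[ok], na.rm = TRUE)))
  sf / exp(mean(log(sf)))
}

# method-of-moments NB dispersion per gene from normalized counts, pooled
# across condition groups; var(y/s) ~ mu * mean(1/s) + alpha * mu^2
.mom_dispersion <- function(counts, sf, group, floor = 1e-8) {
  norm <- sweep(counts, 2L, sf, "/")
  cbar <- tapply(1 / sf, group, mean)
  num <- 0
  den <- 0
  for (g in unique(group)) {
    j <- which(group == g)
    if (length(j) < 2L) next
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1L, stats::var)
    num <- num + (v - m * cbar[[g]])
    den <- den + m^2
  }
  if (all(den == 0)) return(rep(floor, nrow(counts)))
  pmax(num / pmax(den, 1e-12), floor)
}

# vectorized NB MLE of one group's log-mean per gene (log link, offsets
# log(sf), known per-gene dispersion alpha); Newton from the Poisson MLE
.nb_group_logmean <- function(Y, sf, alpha, iter = 10L) {
  tot <- rowSums(Y)
  b <- log((tot + 0.5) / sum(sf))
  for (it in seq_len(iter)) {
    mu <- exp(b) %o% sf
    u <- alpha * mu / (1 + alpha * mu)
    score <- rowSums(Y - (Y + 1 / alpha) * u)
    info <- rowSums((Y + 1 / alpha) * u * (1 - u))
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -5), 5)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  b
}

#' Fit per-gene treatment coefficients from pseudobulk counts
#'
#' A log-linear negative-binomial model of un-normalized pseudobulk counts
#' for one cell line: samples are grouped by condition, depth enters as a
#' median-of-ratios size-factor offset, per-gene dispersion is estimated by
#' method of moments (floored at `min_dispersion`, no shrinkage), and the
#' treatment coefficient of each non-reference condition is the NB MLE
#' log-mean contrast against the reference, on the natural-log scale.
#' Doubling every count of one sample changes its size factor, not the
#' coefficients (offset invariance).
#'
#' @param counts Genes-by-samples non-negative integer matrix (one line's
#'   pseudobulk, un-normalized).
#' @param condition Condition label per sample (>= 2 distinct; each level
#'   needs >= 1 sample).
#' @param reference Reference (vehicle) condition; default the first of
#'   `"vehicle"`, `"DMSO"` or the most common label.
#' @param min_dispersion Dispersion floor.
#' @return Object of class `treatment_fit`: list with `beta` (genes x
#'   non-reference conditions, natural log), `dispersion`, `size_factors`,
#'   `reference`.
#' @export
fit_treatment_model <- function(counts, condition, reference = NULL,
                                min_dispersion = 1e-8) {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(condition))
    stop("condition length != sample columns")
  lev <- unique(condition)
  if (length(lev) < 2L) stop("need >= 2 conditions")
  if (is.null(reference)) {
    reference <- intersect(c("vehicle", "DMSO"), lev)[1L]
    if (is.na(reference)) reference <- names(which.max(table(condition)))
  }
  if (!reference %in% lev) stop("reference condition absent")
  if (any(table(condition) == 0L)) stop("empty condition group")
  sf <- .size_factors(counts)
  alpha <- .mom_dispersion(counts, sf, condition, floor = min_dispersion)
  logmean <- sapply(lev, function(g) {
    j <- which(condition == g)
    .nb_group_logmean(counts[, j, drop = FALSE], sf[j], alpha)
  })
  beta <- logmean[, setdiff(lev, reference), drop = FALSE] -
    logmean[, reference]
  rownames(beta) <- rownames(counts)
  structure(list(beta = beta, dispersion = alpha, size_factors = sf,
                 reference = reference),
            class = "treatment_fit")
}

#' Gene-level synergy covariates from single- vs dual-agent models
#'
#' For each gene and line, the synergy covariate is
#' `s = (betaA + betaB) - betaAB`: the additive single-agent expectation
#' minus the dual-agent coefficient. Covariates are averaged across lines,
#' t-tested two-tailed against a bootstrap null that resamples genes'
#' per-line covariate vectors (B draws), standardized into a robust z
#' (median/MAD, so a small planted tail cannot shift the null), and rank
#' ordered
#' (rank 1 = most negative s, i.e. the combination exceeds additivity the
#' most).
#'
#' @param single_fits Named list (by line) of [fit_treatment_model()]
#'   results from the single-agent design (must contain columns `drug_a`
#'   and `drug_b` of `beta`).
#' @param dual_fits Named list (by line, same lines) of fits whose `beta`
#'   contains `combo`.
#' @param drug_a,drug_b,combo Condition names of the two single agents and
#'   the combination.
#' @param B Bootstrap draws.
#' @param seed Seed.
#' @return `data.frame` of class `synergy_fit`: `gene`, `s_mean`, `t`,
#'   `p_value`, `z`, `rank`, with the per-line covariate matrix as
#'   attribute `"s_by_line"`.
#' @export
synergy_covariates <- function(single_fits, dual_fits, drug_a = "A",
                               drug_b = "B", combo = "AB", B = 10000L,
                               seed = 1L) {
  lines <- names(single_fits)
  if (!identical(sort(lines), sort(names(dual_fits))))
    stop("single and dual fits must cover the same lines")
  genes <- rownames(single_fits[[1L]]$beta)
  S <- sapply(lines, function(l) {
    bs <- single_fits[[l]]$beta
    bd <- dual_fits[[l]]$beta
    if (!identical(rownames(bs), genes) || !identical(rownames(bd), genes))
      stop("gene universe mismatch across fits")
    (bs[, drug_a] + bs[, drug_b]) - bd[, combo]
  })
  set.seed(seed)
  s_mean <- rowMeans(S)
  null <- s_mean[sample.int(length(s_mean), B, replace = TRUE)]
  tt <- (s_mean - mean(null)) / stats::sd(null)
  p <- 2 * stats::pt(-abs(tt), df = B - 1L)
  # robust standardization so a small planted tail cannot shift the null
  z <- (s_mean - stats::median(s_mean)) / stats::mad(s_mean)
  out <- data.frame(gene = genes, s_mean = s_mean, t = tt, p_value = p,
                    z = z, rank = rank(s_mean, ties.method = "first"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "s_by_line") <- S
  class(out) <- c("synergy_fit", "data.frame")
  out
}
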