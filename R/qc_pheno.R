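# Apoptotic-cell flagging, cell-cycle phase scoring and composition tests.

#' Counts-per-10k log-normalized expression
#'
#' The conventional droplet normalization: each cell's counts scaled to
#' 10,000 and log1p-transformed.
#'
#' @param counts Cells-by-genes count matrix (sparse or dense).
#' @return Matrix of the same shape (sparse in, sparse out).
#' @export
normalize_cp10k <- function(counts) {
  tot <- Matrix::rowSums(counts)
  tot[tot == 0] <- 1
  log1p(counts / tot * 1e4)
}

#' Flag apoptotic cells by QC thresholds
#'
#' A cell is flagged when it has fewer detected genes than `min_genes`, OR
#' fewer total counts than `min_counts`, OR a mitochondrially encoded count
#' fraction above `max_mito_frac`. Flags are stored on the experiment and
#' the cells retained: apoptotic cells are themselves a phenotype (their
#' counts per condition are compared downstream), not discarded.
#'
#' @param exp A [pooled_experiment()].
#' @param thr A [qc_thresholds()].
#' @return The experiment with `cell_meta$apoptotic_flag` set.
#' @export
flag_apoptotic <- function(exp, thr = qc_thresholds()) {
  stopifnot(inherits(exp, "pooled_experiment"),
            inherits(thr, "qc_thresholds"))
  n_genes <- Matrix::rowSums(exp$counts > 0)
  n_counts <- Matrix::rowSums(exp$counts)
  mito <- exp$gene_meta$is_mito_encoded
  mito_counts <- if (any(mito)) {
    Matrix::rowSums(exp$counts[, mito, drop = FALSE])
  } else {
    rep(0, nrow(exp$counts))
  }
  mito_frac <- ifelse(n_counts > 0, mito_counts / n_counts, 0)
  exp$cell_meta$apoptotic_flag <-
    n_genes < thr$min_genes | n_counts < thr$min_counts |
    mito_frac > thr$max_mito_frac
  exp
}

#' Score cell-cycle phases from annotated genesets
#'
#' Per cell, each phase score is the mean log-normalized (CP10k) expression
#' of the phase geneset minus the mean of an expression-matched random
#' control set: genes are binned by average expression across cells
#' (`n_bins` equal-frequency bins) and `ctrl_per_gene` control genes are
#' drawn from the bin of each target gene. Phase is G1 when both scores
#' are <= 0, otherwise the phase of the larger score.
#'
#' @param exp A [pooled_experiment()].
#' @param s_genes,g2m_genes Character vectors of S- and G2M-phase gene
#'   symbols; must intersect the gene universe.
#' @param n_bins Expression bins for control matching.
#' @param ctrl_per_gene Control genes drawn per target gene.
#' @param seed Seed for the control draw (deterministic scoring).
#' @return `data.frame`: `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(exp, s_genes, g2m_genes, n_bins = 25L,
                             ctrl_per_gene = 50L, seed = 1L) {
  stopifnot(inherits(exp, "pooled_experiment"))
  expr <- normalize_cp10k(exp$counts)
  universe <- exp$gene_meta$symbol
  s_genes <- intersect(s_genes, universe)
  g2m_genes <- intersect(g2m_genes, universe)
  if (!length(s_genes) || !length(g2m_genes))
    stop("phase geneset(s) disjoint from the gene universe")
  set.seed(seed)
  avg <- Matrix::colMeans(expr)
  bins <- quantize_equal_frequency(avg, min(n_bins, length(avg)))
  score_set <- function(genes) {
    gi <- match(genes, universe)
    ctrl <- unlist(lapply(gi, function(g) {
      pool <- setdiff(which(bins == bins[g]), gi)
      if (!length(pool)) pool <- setdiff(seq_along(avg), gi)
      sample(pool, min(ctrl_per_gene, length(pool)), replace = FALSE)
    }))
    Matrix::rowMeans(expr[, gi, drop = FALSE]) -
      Matrix::rowMeans(expr[, ctrl, drop = FALSE])
  }
  s <- score_set(s_genes)
  g2m <- score_set(g2m_genes)
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  data.frame(barcode = exp$cell_meta$barcode, s_score = as.numeric(s),
             g2m_score = as.numeric(g2m), phase = phase,
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test on a state-by-condition table
#'
#' Tests whether composition (e.g. cell-cycle phase or apoptotic state)
#' shifts across conditions. Standard two-sided Pearson chi-squared with
#' (r-1)(c-1) degrees of freedom, no continuity correction.
#'
#' @param tab Contingency matrix, states in rows, conditions in columns;
#'   all row and column marginals must be positive.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
composition_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal row/column in contingency table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' G1-fraction dose trend
#'
#' OLS of the per-dose G1 fraction on log10(dose) over the non-vehicle
#' doses (a cytostatic drug arrests cells in G1 dose-dependently), with the
#' Pearson-R t-test `t = R * sqrt((n - 2) / (1 - R^2))`. Vehicle (dose 0)
#' points are excluded from the regression; set `anchor_vehicle = TRUE` to
#' first normalize fractions to the vehicle fraction.
#'
#' @param g1_fraction Numeric vector of G1 fractions per dose point.
#' @param dose Matching dose vector (>= 3 non-zero doses required).
#' @param sided `"two"` (default), `"greater"` (arrest increases with
#'   dose) or `"less"`.
#' @param anchor_vehicle Normalize to the mean dose-0 fraction first.
#' @return List: `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
g1_dose_trend <- function(g1_fraction, dose,
                          sided = c("two", "greater", "less"),
                          anchor_vehicle = FALSE) {
  sided <- match.arg(sided)
  stopifnot(length(g1_fraction) == length(dose))
  if (anchor_vehicle) {
    v <- mean(g1_fraction[dose == 0])
    if (!is.finite(v) || v == 0) stop("no vehicle (dose 0) point to anchor on")
    g1_fraction <- g1_fraction / v
  }
  keep <- dose > 0
  x <- log10(dose[keep])
  y <- g1_fraction[keep]
  if (length(x) < 3L) stop("need >= 3 non-zero dose points")
  if (stats::sd(x) == 0) stop("zero variance in log dose")
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- switch(sided,
              two = 2 * stats::pt(-abs(tt), n - 2),
              greater = stats::pt(tt, n - 2, lower.tail = FALSE),
              less = stats::pt(tt, n - 2))
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r = r, p_value = p, n = n)
}
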