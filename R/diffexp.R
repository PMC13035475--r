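# Per-line differential expression and cross-model aggregation: each line
# is a biological replicate of the drug response; per-line log2 fold
# changes are z-normalized within line and averaged across lines, with a
# bootstrap null for significance, group-specific deltas, geneset shift
# tests and the model-downsampling analysis.

#' Per-line log2 fold change with rank-sum p values
#'
#' For one line, the log2 fold change of mean CP10k expression (pseudocount
#' 1) between a drug and a control condition, with a two-sided Wilcoxon
#' rank-sum p per gene (normal approximation with tie correction). A gene
#' absent in both arms gets log2FC 0 and p 1.
#'
#' @param exp A [pooled_experiment()].
#' @param line Line id to test.
#' @param condition,control Condition labels of the two arms.
#' @param min_cells Minimum cells per arm (default 20); fewer raises an
#'   error so callers can skip the line with a warning.
#' @param compute_p Set `FALSE` to skip the rank-sum pass (fold changes
#'   only; much faster for aggregation-only workflows).
#' @return `data.frame`: `gene`, `log2fc`, `p_value` (NA when skipped).
#' @export
per_line_log2fc <- function(exp, line, condition, control,
                            min_cells = 20L, compute_p = TRUE) {
  stopifnot(inherits(exp, "pooled_experiment"))
  cm <- exp$cell_meta
  i_t <- which(cm$line_id == line & cm$condition == condition)
  i_c <- which(cm$line_id == line & cm$condition == control)
  if (length(i_t) < min_cells || length(i_c) < min_cells)
    stop("line ", line, ": fewer than ", min_cells, " cells in an arm (",
         length(i_t), " treated, ", length(i_c), " control)")
  sub <- exp$counts[c(i_t, i_c), , drop = FALSE]
  tot <- Matrix::rowSums(sub)
  tot[tot == 0] <- 1
  cp10k <- sub / tot * 1e4
  nt <- length(i_t)
  m_t <- Matrix::colMeans(cp10k[seq_len(nt), , drop = FALSE])
  m_c <- Matrix::colMeans(cp10k[-seq_len(nt), , drop = FALSE])
  lfc <- log2((m_t + 1) / (m_c + 1))
  p <- rep(NA_real_, length(lfc))
  if (compute_p) {
    X <- as.matrix(cp10k)
    n <- nrow(X)
    n_c <- n - nt
    p <- apply(X, 2L, function(v) {
      r <- rank(v)
      w <- sum(r[seq_len(nt)])
      tie <- table(v)
      s2 <- nt * n_c / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
      if (s2 <= 0) return(1)
      z <- (w - nt * (n + 1) / 2) / sqrt(s2)
      2 * stats::pnorm(-abs(z))
    })
  }
  data.frame(gene = exp$gene_meta$symbol, log2fc = as.numeric(lfc),
             p_value = as.numeric(p), stringsAsFactors = FALSE)
}

#' Per-line log2FC matrix for a set of lines
#'
#' Runs [per_line_log2fc()] over lines, skipping (with a warning) lines
#' with too few cells, and returns the genes-by-lines log2FC matrix that
#' the aggregation functions consume.
#'
#' @inheritParams per_line_log2fc
#' @param lines Line ids (default: all assigned lines present in both
#'   arms).
#' @return Numeric matrix, genes x lines.
#' @export
log2fc_matrix <- function(exp, condition, control, lines = NULL,
                          min_cells = 20L) {
  cm <- exp$cell_meta
  if (is.null(lines))
    lines <- setdiff(sort(unique(cm$line_id)), c("unassigned", "doublet"))
  cols <- list()
  for (l in lines) {
    fc <- tryCatch(per_line_log2fc(exp, l, condition, control,
                                   min_cells = min_cells, compute_p = FALSE),
                   error = function(e) {
                     warning("skipping line ", l, ": ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(fc)) cols[[l]] <- fc$log2fc
  }
  if (!length(cols)) stop("no line passed the cell-count requirement")
  out <- do.call(cbind, cols)
  rownames(out) <- exp$gene_meta$symbol
  out
}

#' Cross-model aggregation of per-line fold changes
#'
#' Treats each line as a biological replicate: per line, log2 fold changes
#' are z-scored across genes; per gene, the line z scores are averaged
#' into a mean difference z. Significance comes from a bootstrap null that
#' resamples genes' line-level z vectors with replacement (preserving the
#' inter-line correlation structure); each gene's mean difference z is
#' t-tested two-tailed against that distribution and BH-corrected.
#' `resample = "lines"` instead resamples line columns (smaller default B).
#'
#' @param fc Genes-by-lines log2FC matrix (>= 2 lines), e.g. from
#'   [log2fc_matrix()].
#' @param B Bootstrap draws.
#' @param resample `"genes"` (default) or `"lines"`.
#' @param seed Seed for the bootstrap.
#' @return `data.frame` of class `cross_model_de`: `gene`, `mean_dz`,
#'   `z`, `p_value`, `q_value`, plus the per-line z matrix as attribute
#'   `"line_z"`.
#' @export
cross_model_aggregate <- function(fc, B = 10000L,
                                  resample = c("genes", "lines"),
                                  seed = 1L) {
  resample <- match.arg(resample)
  fc <- as.matrix(fc)
  if (ncol(fc) < 2L)
    stop("single line: cross-model aggregation needs >= 2 lines; ",
         "use the per-line results directly")
  set.seed(seed)
  z <- scale(fc)
  mdz <- rowMeans(z)
  if (resample == "genes") {
    null <- mdz[sample.int(nrow(z), B, replace = TRUE)]
  } else {
    B <- min(B, 1000L)
    null <- vapply(seq_len(B), function(b) {
      mean(rowMeans(z[, sample.int(ncol(z), replace = TRUE), drop = FALSE]))
    }, numeric(1))
  }
  m <- mean(null)
  s <- stats::sd(null)
  tt <- (mdz - m) / s
  p <- 2 * stats::pt(-abs(tt), df = B - 1L)
  out <- data.frame(gene = rownames(fc) %||% as.character(seq_len(nrow(fc))),
                    mean_dz = mdz, z = tt, p_value = p,
                    q_value = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "line_z") <- z
  class(out) <- c("cross_model_de", "data.frame")
  out
}

#' Group-specific fold-change delta
#'
#' Per gene, the difference in mean log2FC between two groups of lines
#' (e.g. 8 G12C-mutant vs 2 non-G12C lines), with a two-tailed Welch t
#' test. With fewer than 2 lines in a group the delta is retained and the
#' p value reported as missing.
#'
#' @param fc Genes-by-lines log2FC matrix.
#' @param group1,group2 Line ids (column names) of the two groups.
#' @return `data.frame`: `gene`, `delta` (mean group1 - mean group2),
#'   `t`, `p_value`.
#' @export
group_delta <- function(fc, group1, group2) {
  fc <- as.matrix(fc)
  g1 <- fc[, intersect(group1, colnames(fc)), drop = FALSE]
  g2 <- fc[, intersect(group2, colnames(fc)), drop = FALSE]
  if (!ncol(g1) || !ncol(g2)) stop("both groups must be non-empty")
  m1 <- rowMeans(g1)
  m2 <- rowMeans(g2)
  delta <- m1 - m2
  if (ncol(g1) >= 2L && ncol(g2) >= 2L) {
    v1 <- apply(g1, 1L, stats::var) / ncol(g1)
    v2 <- apply(g2, 1L, stats::var) / ncol(g2)
    tt <- delta / sqrt(v1 + v2)
    df <- (v1 + v2)^2 /
      (v1^2 / (ncol(g1) - 1L) + v2^2 / (ncol(g2) - 1L))
    p <- 2 * stats::pt(-abs(tt), df)
  } else {
    tt <- rep(NA_real_, length(delta))
    p <- rep(NA_real_, length(delta))
  }
  data.frame(gene = rownames(fc) %||% as.character(seq_along(delta)),
             delta = delta, t = tt, p_value = p, stringsAsFactors = FALSE)
}

#' Geneset shift test against a background
#'
#' Tests whether a geneset's per-gene statistics (fold changes, z scores)
#' are shifted relative to background genes, reporting both a two-sided
#' Mann-Whitney U p and a two-sample t p together with the direction. A
#' set identical to its background carries no contrast and returns p = 1.
#'
#' @param statistic Named per-gene numeric vector.
#' @param geneset Character vector of member genes (non-empty after
#'   intersection with the statistic's names).
#' @param background Character vector of background genes; defaults to all
#'   non-member genes of the statistic.
#' @return List: `p_mw`, `p_t`, `direction` (+1 set above background),
#'   `set_mean`, `background_mean`, `n_set`, `n_background`.
#' @export
geneset_shift_test <- function(statistic, geneset, background = NULL) {
  genes <- names(statistic)
  if (is.null(genes)) stop("statistic must be a named vector")
  set <- intersect(geneset, genes)
  if (!length(set)) stop("geneset disjoint from the statistic's genes")
  if (is.null(background)) background <- setdiff(genes, set)
  bg <- intersect(background, genes)
  if (!length(bg)) stop("background disjoint from the statistic's genes")
  if (setequal(set, bg)) {
    return(list(p_mw = 1, p_t = 1, direction = 0,
                set_mean = mean(statistic[set]),
                background_mean = mean(statistic[bg]),
                n_set = length(set), n_background = length(bg)))
  }
  xs <- statistic[set]
  xb <- statistic[bg]
  p_mw <- suppressWarnings(stats::wilcox.test(xs, xb, exact = FALSE)$p.value)
  p_t <- stats::t.test(xs, xb)$p.value
  list(p_mw = p_mw, p_t = p_t,
       direction = sign(mean(xs) - mean(xb)),
       set_mean = mean(xs), background_mean = mean(xb),
       n_set = length(set), n_background = length(bg))
}

#' Model-downsampling significance curves
#'
#' Rare is the pool with many models of one genotype; this asks how many
#' are enough. For each subset size k, `n_draws` random line subsets are
#' drawn, the cross-model aggregation is rerun on the subset, and each
#' geneset's shift p value recorded; random genesets of matched size give
#' the flat null curve. With k equal to the number of lines the full
#' analysis is reproduced in a single draw.
#'
#' @param fc Genes-by-lines log2FC matrix.
#' @param ks Subset sizes (each in `2:ncol(fc)`).
#' @param genesets Named list of target genesets.
#' @param n_draws Random subsets per k.
#' @param n_random Random genesets forming the null curve.
#' @param random_size Genes per random set (default: median target size).
#' @param B Bootstrap draws per aggregation rerun.
#' @param seed Seed.
#' @return `data.frame`: `k`, `geneset`, `type` (`"target"`/`"random"`),
#'   `median_p`, `median_neglog10_p`.
#' @export
downsample_models <- function(fc, ks = NULL, genesets, n_draws = 20L,
                              n_random = 20L, random_size = NULL,
                              B = 2000L, seed = 1L) {
  fc <- as.matrix(fc)
  n_lines <- ncol(fc)
  if (is.null(ks)) ks <- 2:n_lines
  if (any(ks < 2L | ks > n_lines)) stop("k out of range 2..", n_lines)
  set.seed(seed)
  genes <- rownames(fc)
  if (is.null(random_size))
    random_size <- as.integer(stats::median(lengths(genesets)))
  rand_sets <- lapply(seq_len(n_random), function(i)
    sample(genes, random_size))
  names(rand_sets) <- paste0("random", seq_len(n_random))
  all_sets <- c(genesets, rand_sets)
  type <- rep(c("target", "random"), c(length(genesets), n_random))

  rows <- list()
  for (k in ks) {
    draws <- if (k == n_lines) 1L else n_draws
    pmat <- matrix(NA_real_, draws, length(all_sets))
    for (d in seq_len(draws)) {
      sub <- fc[, sample.int(n_lines, k), drop = FALSE]
      agg <- cross_model_aggregate(sub, B = B,
                                   seed = sample.int(.Machine$integer.max, 1L))
      stat <- stats::setNames(agg$mean_dz, agg$gene)
      pmat[d, ] <- vapply(all_sets, function(s)
        geneset_shift_test(stat, s)$p_mw, numeric(1))
    }
    med <- apply(pmat, 2L, stats::median)
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, geneset = names(all_sets), type = type, median_p = med,
      median_neglog10_p = -log10(pmax(med, .Machine$double.xmin)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
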