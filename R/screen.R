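# Pooled CRISPRi screen scoring: per-guide treated-vs-vehicle z from a
# read-proportion model, rank-based inverse-normal normalization, and
# per-gene combined rho with BH correction and annotation-group tests.

#' Per-guide enrichment z between treatment arms
#'
#' Counts are summed within arm (per-replicate modeling available via
#' `collapse_reps = FALSE`, which averages replicate z scores) and each
#' guide's read proportion compared between treated and vehicle by the
#' two-proportion z statistic, the Wald statistic of a binomial logit
#' model of per-read arm membership weighted by total reads. Positive z =
#' enriched under treatment. Guides absent from every sample are dropped
#' with a warning.
#'
#' @param guides `data.frame` with `guide_id`, `gene`, and one count
#'   column per sample.
#' @param design `data.frame` with `sample`, `arm` (`"treated"` /
#'   `"vehicle"`).
#' @param libsizes Optional named total-read vector; defaults to the
#'   column sums.
#' @param collapse_reps Sum replicate counts within arm before the
#'   statistic (default) or average per-replicate-pair z scores.
#' @return `data.frame`: `guide_id`, `gene`, `z`.
#' @export
guide_z <- function(guides, design, libsizes = NULL, collapse_reps = TRUE) {
  stopifnot(all(c("guide_id", "gene") %in% names(guides)),
            all(c("sample", "arm") %in% names(design)))
  cnt <- as.matrix(guides[, design$sample, drop = FALSE])
  if (is.null(libsizes)) libsizes <- colSums(cnt)
  libsizes <- libsizes[design$sample]
  if (any(libsizes <= 0)) stop("library sizes must be positive")
  t_j <- design$arm == "treated"
  if (!any(t_j) || !all(t_j | design$arm == "vehicle"))
    stop("design arms must be 'treated' and 'vehicle'")

  two_prop_z <- function(x1, n1, x2, n2) {
    p1 <- x1 / n1
    p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    ifelse(se > 0, (p1 - p2) / se, 0)
  }

  present <- rowSums(cnt) > 0
  if (any(!present))
    warning(sum(!present), " guide(s) absent everywhere dropped")

  if (collapse_reps) {
    z <- two_prop_z(rowSums(cnt[, t_j, drop = FALSE]), sum(libsizes[t_j]),
                    rowSums(cnt[, !t_j, drop = FALSE]), sum(libsizes[!t_j]))
  } else {
    ti <- which(t_j)
    vi <- which(!t_j)
    pairs <- cbind(ti, vi[((seq_along(ti) - 1L) %% length(vi)) + 1L])
    zs <- apply(pairs, 1L, function(pr)
      two_prop_z(cnt[, pr[1L]], libsizes[pr[1L]],
                 cnt[, pr[2L]], libsizes[pr[2L]]))
    z <- rowMeans(zs)
  }
  data.frame(guide_id = guides$guide_id, gene = guides$gene, z = z,
             stringsAsFactors = FALSE)[present, , drop = FALSE]
}

#' Rank-based inverse-normal transform
#'
#' Deterministic normalization of guide z scores: Blom-offset rank INT,
#' `qnorm((rank - 3/8) / (n + 1/4))`. Strictly monotone in the input, so
#' downstream rankings are preserved.
#'
#' @param z Numeric vector (>= 10 values).
#' @return Normalized vector, mean ~0, SD ~1.
#' @export
normalize_z <- function(z) {
  n <- length(z)
  if (n < 10L) stop("need >= 10 values")
  if (mean(duplicated(z)) > 0.5)
    warning("more than half the values are ties; normalization is coarse")
  stats::qnorm((rank(z, ties.method = "average") - 0.375) / (n + 0.25))
}

#' Combine guide z scores into per-gene rho
#'
#' Stouffer combination per gene: `rho = mean(z) * sqrt(k)` over the
#' gene's k guides, two-tailed standard-normal p, BH correction across
#' genes. Non-targeting controls (gene label `control_label`) are scored
#' too but excluded from the BH family. Optional annotations mark
#' protective/sensitizing candidates.
#'
#' @param guide_tab Output of [guide_z()] (after [normalize_z()] on `z`).
#' @param annotations Optional named vector gene -> annotation (e.g.
#'   `"protective"`, `"sensitizing"`).
#' @param control_label Gene label of non-targeting controls.
#' @return `data.frame` of class `gene_rho`: `gene`, `rho`, `n_guides`,
#'   `p_value`, `q_value`, `annotation`.
#' @export
gene_rho <- function(guide_tab, annotations = NULL,
                     control_label = "control") {
  stopifnot(all(c("gene", "z") %in% names(guide_tab)))
  sp <- split(guide_tab$z, guide_tab$gene)
  rho <- vapply(sp, function(z) mean(z) * sqrt(length(z)), numeric(1))
  k <- lengths(sp)
  p <- 2 * stats::pnorm(-abs(rho))
  is_ctrl <- names(sp) == control_label
  q <- rep(NA_real_, length(p))
  q[!is_ctrl] <- stats::p.adjust(p[!is_ctrl], "BH")
  ann <- rep("unannotated", length(rho))
  if (!is.null(annotations)) {
    hit <- match(names(sp), names(annotations))
    ann[!is.na(hit)] <- annotations[hit[!is.na(hit)]]
  }
  out <- data.frame(gene = names(sp), rho = unname(rho),
                    n_guides = unname(k), p_value = unname(p),
                    q_value = q, annotation = ann, stringsAsFactors = FALSE)
  out <- out[order(out$rho), ]
  rownames(out) <- NULL
  class(out) <- c("gene_rho", "data.frame")
  out
}

#' Annotation-group and cross-screen rho tests
#'
#' Per annotation group, a one-sample two-tailed t test of the member
#' genes' rho against 0, with the mean direction reported (protective
#' candidates are expected positive under drug, sensitizing negative).
#' Groups smaller than 3 report the mean with the p withheld. When a
#' second screen's [gene_rho()] table is supplied, a two-sample t test of
#' shared genes' rho between the screens is added (`screen_comparison`).
#'
#' @param rho_tab A [gene_rho()] table with an `annotation` column.
#' @param other Optional second `gene_rho` table for the across-model
#'   comparison.
#' @param genes Optional gene subset for the across-model comparison.
#' @return List: `groups` (`annotation`, `n`, `mean_rho`, `t`, `p_value`)
#'   and `screen_comparison` (or NULL).
#' @export
rho_group_test <- function(rho_tab, other = NULL, genes = NULL) {
  grp <- setdiff(unique(rho_tab$annotation), "unannotated")
  groups <- do.call(rbind, lapply(grp, function(g) {
    r <- rho_tab$rho[rho_tab$annotation == g]
    if (length(r) >= 3L) {
      ht <- stats::t.test(r, mu = 0)
      data.frame(annotation = g, n = length(r), mean_rho = mean(r),
                 t = unname(ht$statistic), p_value = ht$p.value,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(annotation = g, n = length(r), mean_rho = mean(r),
                 t = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
    }
  }))
  cmp <- NULL
  if (!is.null(other)) {
    shared <- intersect(rho_tab$gene, other$gene)
    if (!is.null(genes)) shared <- intersect(shared, genes)
    r1 <- rho_tab$rho[match(shared, rho_tab$gene)]
    r2 <- other$rho[match(shared, other$gene)]
    ht <- stats::t.test(r1, r2)
    cmp <- list(n = length(shared), mean_diff = mean(r1) - mean(r2),
                t = unname(ht$statistic), p_value = ht$p.value)
  }
  list(groups = groups, screen_comparison = cmp)
}
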