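# Sample (hash) and line-of-origin (genotype) assignment with doublet
# detection. The genotype model scores each cell's ref/alt reads against
# every line's dosages and against every unordered line pair mixed at
# alpha = 0.5, then calls the maximum-posterior hypothesis.

#' One-dimensional Otsu split
#'
#' Deterministic two-class threshold maximizing between-class variance;
#' used to decide per-channel hashtag positivity.
#'
#' @param x Numeric vector (length >= 2, non-constant for a meaningful
#'   split).
#' @return The threshold value; points strictly above it form the upper
#'   class.
#' @keywords internal
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L || x[1] == x[n]) return(Inf)
  cs <- cumsum(x)
  k <- seq_len(n - 1L)
  m0 <- cs[k] / k
  m1 <- (cs[n] - cs[k]) / (n - k)
  bcv <- (k / n) * (1 - k / n) * (m0 - m1)^2
  i <- which.max(bcv)
  (x[i] + x[i + 1L]) / 2
}

#' Assign cells to hashed samples
#'
#' Hashtag counts are centered-log-ratio transformed within each cell and
#' each channel is thresholded across cells by a one-dimensional Otsu
#' split. A cell positive for exactly one channel is assigned to that
#' sample; two or more positive channels call a hash doublet; zero positive
#' channels (including all-zero cells) are unassigned.
#'
#' @param hash_counts Cells-by-channels matrix of HTO counts; column names
#'   are the sample ids.
#' @return `data.frame` with `barcode` (rownames if present), `hash_call`
#'   (sample id, `"doublet"` or `"unassigned"`) and `n_positive`.
#' @export
assign_hash <- function(hash_counts) {
  hash_counts <- as.matrix(hash_counts)
  if (ncol(hash_counts) < 1L) stop("need >= 1 hash channel")
  lg <- log1p(hash_counts)
  clr <- lg - rowMeans(lg)
  thr <- apply(clr, 2L, otsu_threshold)
  pos <- sweep(clr, 2L, thr, ">") & hash_counts > 0
  np <- rowSums(pos)
  call <- rep("unassigned", nrow(hash_counts))
  one <- np == 1L
  call[one] <- colnames(hash_counts)[max.col(pos[one, , drop = FALSE],
                                             ties.method = "first")]
  call[np >= 2L] <- "doublet"
  data.frame(barcode = rownames(hash_counts) %||%
               as.character(seq_len(nrow(hash_counts))),
             hash_call = call, n_positive = np, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-read singlet log-likelihood of a dosage vector
#'
#' Sum over covered variants of `alt * log(p) + ref * log(1 - p)` with
#' `p = (1 - err) * d + err * (1 - d)`: the log of the per-read product
#' likelihood (the binomial coefficient, constant across candidate lines,
#' is omitted). Variants with an uncalled (`NA`) dosage are skipped; with
#' no covered variants the value is 0.
#'
#' @param alt,ref Integer read counts per variant.
#' @param dosage Alt-allele dosage per variant in {0, 0.5, 1, NA}.
#' @param err Per-read error rate, in (0, 0.5).
#' @return Scalar log-likelihood.
#' @export
singlet_loglik <- function(alt, ref, dosage, err = 0.01) {
  if (err <= 0 || err >= 0.5) stop("err must be in (0, 0.5)")
  keep <- !is.na(dosage) & (alt + ref) > 0
  if (!any(keep)) return(0)
  p <- (1 - err) * dosage[keep] + err * (1 - dosage[keep])
  sum(alt[keep] * log(p) + ref[keep] * log1p(-p))
}

# cells x variants sparse alt/total matrices from a long allele table
.allele_matrices <- function(alleles, reference) {
  bc <- sort(unique(alleles$barcode))
  vi <- match(alleles$variant_id, reference$variant_ids)
  if (anyNA(vi)) stop("allele table names variants absent from reference")
  ci <- match(alleles$barcode, bc)
  V <- length(reference$variant_ids)
  alt <- Matrix::sparseMatrix(i = ci, j = vi, x = alleles$alt_reads,
                              dims = c(length(bc), V),
                              dimnames = list(bc, reference$variant_ids))
  ref <- Matrix::sparseMatrix(i = ci, j = vi, x = alleles$ref_reads,
                              dims = c(length(bc), V),
                              dimnames = list(bc, reference$variant_ids))
  list(alt = alt, ref = ref, barcodes = bc)
}

# log p / log(1-p) columns for a set of dosage columns; NA dosage -> 0
# contribution (variant skipped for that hypothesis)
.loglik_block <- function(alt, ref, P, err) {
  p <- (1 - err) * P + err * (1 - P)
  lp <- log(p)
  lq <- log1p(-p)
  lp[is.na(lp)] <- 0
  lq[is.na(lq)] <- 0
  as.matrix(alt %*% lp + ref %*% lq)
}

#' Genotype-demultiplex cells against a line reference
#'
#' For every cell the per-read likelihood of each candidate line (singlet)
#' and of each unordered line pair mixed at `alpha` (doublet) is computed
#' from its ref/alt reads; the call is the maximum-posterior hypothesis
#' with prior mass `1 - doublet_prior` spread over singlets and
#' `doublet_prior` over pairs. Cells with fewer than `min_reads`
#' informative reads are called `ambiguous`.
#'
#' @param alleles An [allele_counts()] table.
#' @param reference A [genotype_reference()] with >= 2 lines.
#' @param err Per-read error rate in (0, 0.5).
#' @param doublet_prior Prior probability that a droplet holds two cells.
#' @param alpha Mixing proportion of the doublet model (first line's
#'   share); 0.5 models an equal two-cell mixture.
#' @param min_reads Minimum informative reads for a confident call.
#' @return `data.frame` of class `demux_calls`: `barcode`, `call`
#'   (`"singlet"`, `"doublet"`, `"ambiguous"`), `line` (best singlet line),
#'   `doublet_pair` (e.g. `"L1+L3"`, unordered), `ll_singlet`,
#'   `ll_doublet`, `margin` (log-posterior gap between best and
#'   second-best hypothesis), `n_reads`.
#' @export
assign_genotype <- function(alleles, reference, err = 0.01,
                            doublet_prior = 0.05, alpha = 0.5,
                            min_reads = 10L) {
  if (err <= 0 || err >= 0.5) stop("err must be in (0, 0.5)")
  stopifnot(inherits(reference, "genotype_reference"))
  L <- length(reference$line_ids)
  if (L < 2L) stop("reference must contain >= 2 lines")
  am <- .allele_matrices(alleles, reference)
  D <- t(reference$dosage)                       # variants x lines
  ll_s <- .loglik_block(am$alt, am$ref, D, err)  # cells x lines
  pairs <- utils::combn(L, 2L)
  Dp <- alpha * D[, pairs[1L, ], drop = FALSE] +
    (1 - alpha) * D[, pairs[2L, ], drop = FALSE]
  ll_d <- .loglik_block(am$alt, am$ref, Dp, err) # cells x pairs
  n_pairs <- ncol(pairs)
  pair_names <- paste(reference$line_ids[pairs[1L, ]],
                      reference$line_ids[pairs[2L, ]], sep = "+")

  lpost <- cbind(ll_s + log((1 - doublet_prior) / L),
                 ll_d + log(doublet_prior / n_pairs))
  n_reads <- Matrix::rowSums(am$alt) + Matrix::rowSums(am$ref)
  best <- max.col(lpost, ties.method = "first")
  second <- apply(lpost, 1L, function(v) -sort(-v, partial = 2L)[2L])
  margin <- lpost[cbind(seq_len(nrow(lpost)), best)] - second

  bi_s <- max.col(ll_s, ties.method = "first")
  bi_d <- max.col(ll_d, ties.method = "first")
  call <- ifelse(best <= L, "singlet", "doublet")
  call[n_reads < min_reads] <- "ambiguous"
  out <- data.frame(
    barcode = am$barcodes, call = call,
    line = reference$line_ids[bi_s],
    doublet_pair = pair_names[bi_d],
    ll_singlet = ll_s[cbind(seq_along(bi_s), bi_s)],
    ll_doublet = ll_d[cbind(seq_along(bi_d), bi_d)],
    margin = margin, n_reads = as.integer(n_reads),
    stringsAsFactors = FALSE)
  class(out) <- c("demux_calls", "data.frame")
  out
}

#' Map expression clusters to lines by pseudobulk allele correlation
#'
#' Pools each cluster's ref/alt reads into per-variant alt-allele
#' fractions and assigns the line whose reference dosages correlate best
#' (Pearson). Ties are broken by line order with a warning; clusters with
#' fewer than two informative variants are unassigned.
#'
#' @param clusters Named vector (names = barcodes) or data.frame
#'   (`barcode`, `cluster`) of cluster labels.
#' @param alleles An [allele_counts()] table.
#' @param reference A [genotype_reference()].
#' @return `data.frame`: `cluster`, `line`, `correlation`, `n_variants`.
#' @export
assign_clusters_by_pseudobulk <- function(clusters, alleles, reference) {
  if (is.data.frame(clusters)) {
    clusters <- stats::setNames(clusters$cluster, clusters$barcode)
  }
  cl <- clusters[alleles$barcode]
  if (anyNA(cl)) stop("some allele barcodes have no cluster label")
  D <- reference$dosage                          # lines x variants
  out <- lapply(sort(unique(cl)), function(k) {
    sub <- alleles[cl == k, , drop = FALSE]
    alt <- tapply(sub$alt_reads, sub$variant_id, sum)
    tot <- tapply(sub$alt_reads + sub$ref_reads, sub$variant_id, sum)
    frac <- alt / tot
    vi <- match(names(frac), reference$variant_ids)
    r <- apply(D[, vi, drop = FALSE], 1L, function(d) {
      keep <- !is.na(d) & is.finite(frac)
      if (sum(keep) < 2L || stats::sd(d[keep]) == 0 ||
          stats::sd(frac[keep]) == 0) return(NA_real_)
      stats::cor(frac[keep], d[keep])
    })
    if (all(is.na(r))) {
      return(data.frame(cluster = k, line = "unassigned",
                        correlation = NA_real_,
                        n_variants = length(frac), stringsAsFactors = FALSE))
    }
    top <- which(r == max(r, na.rm = TRUE))
    if (length(top) > 1L)
      warning("cluster ", k, ": correlation tie broken by line order (",
              paste(reference$line_ids[top], collapse = ", "), ")")
    data.frame(cluster = k, line = reference$line_ids[top[1L]],
               correlation = max(r, na.rm = TRUE),
               n_variants = length(frac), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
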