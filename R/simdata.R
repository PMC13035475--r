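# Synthetic pooled experiments with known ground truth.
#
# The generator collapses growth and treatment into per-condition sampling
# weights (the assay's readout is end-point representation, not dynamics):
# a cell's line is drawn multinomially with weight
#   base_weight * exp(r * t_growth) * survival_fraction(dose),
# gene counts are negative binomial around per-line expression profiles with
# planted log2 program shifts in treated survivors, doublets sum two cells'
# counts, and apoptotic cells get depressed totals plus an inflated
# mitochondrial share so that they cross the QC thresholds.

#' Per-line specification table for the simulator
#'
#' @param id Line identifiers.
#' @param growth_rate Exponential growth rate r per hour.
#' @param base_weight Baseline pool weight (seeding share).
#' @param max_kill Maximum kill fraction at saturating dose, in `[0, 1]`.
#' @param log10_ic50 log10 of the dose of half-maximal kill (drug units).
#' @param hill Hill slope of the survival curve.
#' @return `data.frame` with one row per line.
#' @export
sim_lines <- function(id, growth_rate = 0, base_weight = 1, max_kill = 0,
                      log10_ic50 = 0, hill = 1) {
  df <- data.frame(id = as.character(id), growth_rate = growth_rate,
                   base_weight = base_weight, max_kill = max_kill,
                   log10_ic50 = log10_ic50, hill = hill,
                   stringsAsFactors = FALSE)
  if (any(df$base_weight <= 0)) stop("base_weight must be positive")
  if (any(df$max_kill < 0 | df$max_kill > 1)) stop("max_kill must be in [0,1]")
  df
}

#' Hill-form survival fraction
#'
#' `1 - max_kill * dose^h / (10^(h*log10_ic50) + dose^h)`; equals 1 at dose
#' 0. The functional form is a simulator choice (a standard pharmacology
#' parameterization), not a claim about any particular dataset.
#'
#' @param dose Non-negative dose (drug units).
#' @param max_kill,log10_ic50,hill Curve parameters, see [sim_lines()].
#' @return Survival fraction in `[1 - max_kill, 1]`.
#' @export
hill_survival <- function(dose, max_kill, log10_ic50, hill = 1) {
  n <- max(length(dose), length(max_kill), length(log10_ic50), length(hill))
  dose <- rep_len(dose, n)
  max_kill <- rep_len(max_kill, n)
  log10_ic50 <- rep_len(log10_ic50, n)
  hill <- rep_len(hill, n)
  s <- 1 - max_kill * dose^hill / (10^(log10_ic50 * hill) + dose^hill)
  s[dose <= 0] <- 1
  s
}

#' Simulator configuration
#'
#' Bundles every knob of [simulate_pool()]. Defaults emulate a pooled
#' multi-line 3D-culture experiment: vehicle plus one drug arm, 6 days of
#' growth, lognormal library sizes around 10,000 UMIs over a 2,000-gene
#' universe with a ~8% mitochondrial share in healthy cells.
#'
#' @param lines A [sim_lines()] table.
#' @param conditions `data.frame` with columns `condition`, `dose`,
#'   `n_reps`. Dose 0 rows are vehicle.
#' @param programs List of planted expression programs, each a list with
#'   `name`, `genes` (symbols), `log2_shift`, and `lines` (ids the shift
#'   applies to); applied to treated (dose > 0) cells only.
#' @param n_genes,n_mito_genes Gene-universe size and number of
#'   mitochondrially encoded genes (symbols `MT-1`, ...).
#' @param cells_per_sample Droplets per hashed sample.
#' @param nb_dispersion Global NB dispersion (var = mu + a*mu^2).
#' @param libsize_meanlog,libsize_sdlog Lognormal library-size parameters.
#' @param mito_share Share of expression on mito-encoded genes in healthy
#'   cells.
#' @param line_expr_sd Lognormal sd of line-specific expression deviation.
#' @param doublet_rate Fraction of droplets holding two cells (two distinct
#'   lines).
#' @param hash_signal,hash_background,hash_error HTO signal/background mean
#'   counts and the rate at which a cell's own channel fails to stain.
#' @param apoptotic_rate,apoptotic_scale,apoptotic_mito_boost Fraction of
#'   apoptotic cells, their library-size multiplier, and the factor by which
#'   their mitochondrial expression share is inflated.
#' @param n_clusters,confined_fraction Ground-truth cluster labels per line:
#'   treated cells fall into cluster 1 with probability `confined_fraction`
#'   (planted heterogeneity of survival), otherwise uniformly.
#' @param t_growth Growth horizon in hours entering the sampling weights
#'   (144 h = the 6-day treatment window).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(lines,
                       conditions = data.frame(condition = c("DMSO", "drug"),
                                               dose = c(0, 1), n_reps = 1L),
                       programs = list(),
                       n_genes = 2000L, n_mito_genes = 13L,
                       cells_per_sample = 2000L,
                       nb_dispersion = 0.3,
                       libsize_meanlog = log(1e4), libsize_sdlog = 0.3,
                       mito_share = 0.08, line_expr_sd = 0.3,
                       doublet_rate = 0, hash_signal = 200,
                       hash_background = 2, hash_error = 0.01,
                       apoptotic_rate = 0, apoptotic_scale = 0.08,
                       apoptotic_mito_boost = 10,
                       n_clusters = 10L, confined_fraction = 0,
                       t_growth = 144, seed = 1L) {
  if (nrow(lines) == 0L) stop("empty line list")
  stopifnot(all(c("condition", "dose", "n_reps") %in% names(conditions)))
  rates <- c(doublet_rate, hash_error, apoptotic_rate, confined_fraction)
  if (any(rates < 0 | rates >= 1 + 1e-12) || doublet_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (n_mito_genes >= n_genes) stop("n_mito_genes must be < n_genes")
  for (p in programs) {
    stopifnot(all(c("name", "genes", "log2_shift", "lines") %in% names(p)))
  }
  structure(as.list(environment()), class = "sim_config")
}

# per-profile expression table: rows indexed by (line, shifted, apoptotic)
.sim_profiles <- function(cfg, symbols, is_mito) {
  G <- cfg$n_genes
  base <- stats::rgamma(G, shape = 0.6, rate = 1) + 0.02
  # pin the healthy-cell mitochondrial share
  base[is_mito] <- base[is_mito] *
    (cfg$mito_share / (1 - cfg$mito_share)) * sum(base[!is_mito]) /
    sum(base[is_mito])
  nl <- nrow(cfg$lines)
  E <- matrix(base, nl, G, byrow = TRUE) *
    exp(matrix(stats::rnorm(nl * G, 0, cfg$line_expr_sd), nl, G))
  rownames(E) <- cfg$lines$id
  colnames(E) <- symbols
  E
}

.apply_programs <- function(expr_row, line, cfg, symbols) {
  for (p in cfg$programs) {
    if (line %in% p$lines) {
      j <- match(p$genes, symbols)
      if (anyNA(j)) stop("program '", p$name, "' names unknown genes")
      expr_row[j] <- expr_row[j] * 2^p$log2_shift
    }
  }
  expr_row
}

#' Simulate a pooled multi-line drug-response experiment
#'
#' Generates a [pooled_experiment()] together with its ground truth and the
#' observed hashtag count matrix. Per hashed sample, each droplet's line is
#' drawn multinomially with weights `base_weight * exp(r * t_growth) *
#' survival(dose)`; treated cells of program lines carry the planted log2
#' shifts; a `doublet_rate` fraction of droplets holds two cells of distinct
#' lines whose counts are summed; apoptotic cells get `apoptotic_scale`
#' library sizes with mitochondrial expression inflated by
#' `apoptotic_mito_boost`.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `experiment` ([pooled_experiment()] carrying
#'   the true labels), `truth` (list: `cells` per-droplet table with true
#'   line/partner/cluster/apoptotic state, `survival` per line-dose table,
#'   `expected_fraction` lines-by-samples matrix, `programs`), and
#'   `hash_counts` (droplets x samples HTO matrix).
#' @export
simulate_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  symbols <- c(paste0("MT-", seq_len(cfg$n_mito_genes)),
               paste0("G", seq_len(G - cfg$n_mito_genes)))
  is_mito <- is_mito_symbol(symbols)
  E <- .sim_profiles(cfg, symbols, is_mito)
  lines <- cfg$lines
  nl <- nrow(lines)

  cond <- cfg$conditions
  samples <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    data.frame(condition = cond$condition[i], dose = cond$dose[i],
               replicate = paste0("r", seq_len(cond$n_reps[i])),
               stringsAsFactors = FALSE)
  }))
  samples$sample_id <- sprintf("%s_d%g_%s", samples$condition, samples$dose,
                               samples$replicate)

  # expected line weights per sample
  W <- vapply(seq_len(nrow(samples)), function(s) {
    surv <- hill_survival(samples$dose[s], lines$max_kill, lines$log10_ic50,
                          lines$hill)
    w <- lines$base_weight * exp(lines$growth_rate * cfg$t_growth) * surv
    w / sum(w)
  }, numeric(nl))
  W <- matrix(W, nrow = nl,
              dimnames = list(lines$id, samples$sample_id))

  all_counts <- vector("list", nrow(samples))
  all_cells <- vector("list", nrow(samples))
  all_hash <- vector("list", nrow(samples))

  for (s in seq_len(nrow(samples))) {
    n <- cfg$cells_per_sample
    n_doub <- round(cfg$doublet_rate * n)
    n_sing <- n - n_doub
    w <- W[, s]
    treated <- samples$dose[s] > 0

    line1 <- sample.int(nl, n, replace = TRUE, prob = w)
    line2 <- rep(NA_integer_, n)
    if (n_doub > 0L) {
      di <- seq_len(n_doub) + n_sing
      line2[di] <- vapply(line1[di], function(l1) {
        w2 <- w
        w2[l1] <- 0
        sample.int(nl, 1L, prob = w2)
      }, integer(1))
    }
    apop <- stats::runif(n) < cfg$apoptotic_rate
    libsize <- stats::rlnorm(n, cfg$libsize_meanlog, cfg$libsize_sdlog)
    libsize[apop] <- libsize[apop] * cfg$apoptotic_scale

    cluster <- sample.int(cfg$n_clusters, n, replace = TRUE)
    if (treated && cfg$confined_fraction > 0) {
      conf <- stats::runif(n) < cfg$confined_fraction
      cluster[conf] <- 1L
    }

    # expression profile per member; planted programs act on treated cells
    mu1 <- E[line1, , drop = FALSE]
    if (treated && length(cfg$programs)) {
      for (i in seq_len(n)) {
        mu1[i, ] <- .apply_programs(mu1[i, ], lines$id[line1[i]], cfg,
                                    symbols)
      }
    }
    if (any(apop)) {
      mu1[apop, is_mito] <- mu1[apop, is_mito] * cfg$apoptotic_mito_boost
    }
    mu1 <- mu1 / rowSums(mu1) * libsize
    cnt <- matrix(stats::rnbinom(n * G, mu = mu1, size = 1 / cfg$nb_dispersion),
                  n, G)
    if (n_doub > 0L) {
      di <- seq_len(n_doub) + n_sing
      lib2 <- stats::rlnorm(n_doub, cfg$libsize_meanlog, cfg$libsize_sdlog)
      mu2 <- E[line2[di], , drop = FALSE]
      if (treated && length(cfg$programs)) {
        for (i in seq_len(n_doub)) {
          mu2[i, ] <- .apply_programs(mu2[i, ], lines$id[line2[di][i]], cfg,
                                      symbols)
        }
      }
      mu2 <- mu2 / rowSums(mu2) * lib2
      cnt[di, ] <- cnt[di, ] +
        matrix(stats::rnbinom(n_doub * G, mu = mu2,
                              size = 1 / cfg$nb_dispersion), n_doub, G)
    }

    # HTO counts: own channel signal unless staining failed
    hash <- matrix(stats::rnbinom(n * nrow(samples),
                                  mu = cfg$hash_background, size = 10),
                   n, nrow(samples))
    stained <- stats::runif(n) >= cfg$hash_error
    hash[stained, s] <- stats::rnbinom(sum(stained), mu = cfg$hash_signal,
                                       size = 10)

    bc <- sprintf("%s-c%04d", samples$sample_id[s], seq_len(n))
    all_counts[[s]] <- cnt
    all_hash[[s]] <- hash
    all_cells[[s]] <- data.frame(
      barcode = bc, sample_id = samples$sample_id[s],
      condition = samples$condition[s], dose = samples$dose[s],
      replicate = samples$replicate[s],
      line = lines$id[line1], partner_line = ifelse(is.na(line2), NA,
                                                    lines$id[line2]),
      doublet = !is.na(line2), apoptotic = apop, cluster = cluster,
      stringsAsFactors = FALSE)
  }

  cells <- do.call(rbind, all_cells)
  counts <- Matrix::Matrix(do.call(rbind, all_counts), sparse = TRUE)
  dimnames(counts) <- list(cells$barcode, symbols)
  hash_counts <- do.call(rbind, all_hash)
  dimnames(hash_counts) <- list(cells$barcode, samples$sample_id)

  cell_meta <- data.frame(
    barcode = cells$barcode,
    line_id = ifelse(cells$doublet, "unassigned", cells$line),
    condition = cells$condition, dose = cells$dose,
    replicate = cells$replicate, hash_id = cells$sample_id,
    doublet_flag = cells$doublet, stringsAsFactors = FALSE)
  genesets <- list()
  for (p in cfg$programs) genesets[[p$name]] <- p$genes
  exp <- pooled_experiment(counts, cell_meta, genesets = genesets,
                           vehicle_labels = unique(
                             samples$condition[samples$dose == 0]))

  doses <- sort(unique(samples$dose))
  survival <- do.call(rbind, lapply(doses, function(d) {
    data.frame(line = lines$id, dose = d,
               survival = hill_survival(d, lines$max_kill, lines$log10_ic50,
                                        lines$hill),
               stringsAsFactors = FALSE)
  }))

  list(experiment = exp,
       truth = list(cells = cells, survival = survival,
                    expected_fraction = W, programs = cfg$programs),
       hash_counts = hash_counts)
}

#' Simulate a random per-line genotype reference
#'
#' Dosages are drawn per variant from Hardy-Weinberg-style proportions at a
#' uniform alt-allele frequency, independently per line, with a small rate
#' of uncalled entries.
#'
#' @param n_lines,n_variants Panel dimensions.
#' @param missing_rate Fraction of uncalled (NA) entries.
#' @param maf_range Range of per-variant alt-allele frequencies.
#' @param seed Optional integer seed.
#' @return A [genotype_reference()].
#' @export
simulate_genotype_reference <- function(n_lines, n_variants,
                                        missing_rate = 0.02,
                                        maf_range = c(0.2, 0.8),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::runif(n_variants, maf_range[1], maf_range[2])
  D <- sapply(q, function(qi) {
    sample(c(0, 0.5, 1), n_lines, replace = TRUE,
           prob = c((1 - qi)^2, 2 * qi * (1 - qi), qi^2))
  })
  D[matrix(stats::runif(n_lines * n_variants) < missing_rate,
           n_lines, n_variants)] <- NA
  genotype_reference(D, line_ids = paste0("L", seq_len(n_lines)),
                     variant_ids = sprintf("chr1:%d:A:G", seq_len(n_variants)))
}

#' Simulate per-cell allele read counts
#'
#' Per covered variant, alt reads are Binomial(depth, p) with
#' `p = (1 - err) * d + err * (1 - d)` where d is the cell's line dosage;
#' doublet droplets use the equal (alpha = 0.5) mixture of their two lines'
#' dosages. Per-variant coverage is Poisson with mean `mean_depth /
#' n_variants`, so `mean_depth` is the expected total informative reads per
#' cell. Variants with an uncalled dosage for the cell's line(s) yield no
#' reads.
#'
#' @param truth_cells The `truth$cells` table of [simulate_pool()] (columns
#'   `barcode`, `line`, `partner_line`, `doublet`), or any data.frame with
#'   those columns.
#' @param reference A [genotype_reference()] containing every true line.
#' @param mean_depth Expected informative reads per cell.
#' @param err Per-read base error rate.
#' @param seed Optional integer seed.
#' @return An [allele_counts()] table.
#' @export
simulate_allele_counts <- function(truth_cells, reference, mean_depth = 60,
                                   err = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- reference$dosage
  miss <- setdiff(unique(c(truth_cells$line,
                           stats::na.omit(truth_cells$partner_line))),
                  rownames(D))
  if (length(miss))
    stop("line(s) missing from reference: ", paste(miss, collapse = ", "))
  n <- nrow(truth_cells)
  V <- ncol(D)
  d <- D[truth_cells$line, , drop = FALSE]
  if (any(truth_cells$doublet)) {
    di <- which(truth_cells$doublet)
    d[di, ] <- (d[di, , drop = FALSE] +
                  D[truth_cells$partner_line[di], , drop = FALSE]) / 2
  }
  if (mean_depth <= 0) {
    return(allele_counts(data.frame(barcode = character(0),
                                    variant_id = character(0),
                                    ref_reads = integer(0),
                                    alt_reads = integer(0))))
  }
  cov <- matrix(stats::rpois(n * V, mean_depth / V), n, V)
  cov[is.na(d)] <- 0L
  idx <- which(cov > 0)
  if (!length(idx)) {
    return(allele_counts(data.frame(barcode = character(0),
                                    variant_id = character(0),
                                    ref_reads = integer(0),
                                    alt_reads = integer(0))))
  }
  p <- (1 - err) * d[idx] + err * (1 - d[idx])
  alt <- stats::rbinom(length(idx), cov[idx], p)
  allele_counts(data.frame(
    barcode = truth_cells$barcode[(idx - 1L) %% n + 1L],
    variant_id = colnames(D)[(idx - 1L) %/% n + 1L],
    ref_reads = cov[idx] - alt, alt_reads = alt,
    stringsAsFactors = FALSE), reference = reference)
}

#' Simulate a pooled guide screen
#'
#' Vehicle counts are negative binomial around the library proportions;
#' treated counts multiply each targeting guide's proportion by
#' `2^effect` of its gene (non-targeting controls have effect 0).
#'
#' @param n_genes Number of targeted genes (`GENE1`, ...).
#' @param guides_per_gene Guides per gene (>= 1).
#' @param effects Named numeric vector of planted log2 effects keyed by
#'   gene; genes not named have effect 0.
#' @param n_controls Number of non-targeting control guides (gene label
#'   `"control"`).
#' @param reps Replicates per arm.
#' @param libsize Reads per sample (scalar or one per sample).
#' @param dispersion NB dispersion of counts.
#' @param seed Optional integer seed.
#' @return List: `guides` (guide_id, gene, one count column per sample),
#'   `design` (`sample`, `arm` in {vehicle, treated}), `libsizes` (named),
#'   `truth` (gene, effect).
#' @export
simulate_guide_screen <- function(n_genes = 100, guides_per_gene = 5,
                                  effects = NULL, n_controls = 50,
                                  reps = 2, libsize = 1e6,
                                  dispersion = 0.05, seed = NULL) {
  if (guides_per_gene < 1) stop("guides_per_gene must be >= 1")
  if (any(libsize <= 0)) stop("library sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  gene <- c(rep(paste0("GENE", seq_len(n_genes)), each = guides_per_gene),
            rep("control", n_controls))
  guide_id <- paste0(gene, "_g", unlist(lapply(table(factor(gene, levels = unique(gene))), seq_len)))
  ng <- length(gene)
  eff <- stats::setNames(rep(0, n_genes), paste0("GENE", seq_len(n_genes)))
  if (!is.null(effects)) eff[names(effects)] <- effects
  eff_guide <- ifelse(gene == "control", 0, eff[gene])

  base <- stats::rlnorm(ng, 0, 0.5)
  p0 <- base / sum(base)
  pt <- p0 * 2^eff_guide
  pt <- pt / sum(pt)

  sample_names <- c(paste0("vehicle_r", seq_len(reps)),
                    paste0("treated_r", seq_len(reps)))
  libsize <- rep_len(libsize, 2 * reps)
  cnt <- sapply(seq_len(2 * reps), function(j) {
    p <- if (j <= reps) p0 else pt
    stats::rnbinom(ng, mu = p * libsize[j], size = 1 / dispersion)
  })
  colnames(cnt) <- sample_names
  guides <- data.frame(guide_id = guide_id, gene = gene,
                       stringsAsFactors = FALSE)
  guides <- cbind(guides, as.data.frame(cnt))
  list(guides = guides,
       design = data.frame(sample = sample_names,
                           arm = rep(c("vehicle", "treated"), each = reps),
                           stringsAsFactors = FALSE),
       libsizes = stats::setNames(libsize, sample_names),
       truth = data.frame(gene = names(eff), effect = unname(eff),
                          stringsAsFactors = FALSE))
}

#' Simulate pseudobulk counts for synergy modeling
#'
#' Generates per-line pseudobulk counts for a vehicle / drug A / drug B /
#' combination design. Every gene carries small random single-agent log2
#' effects; a chosen subset additionally carries a non-additive interaction
#' so the combination deviates from the single-agent sum.
#'
#' @param n_genes Gene-universe size.
#' @param n_lines,reps Lines and replicates per line x condition.
#' @param mean_log,mean_sd Lognormal parameters of baseline gene means.
#' @param lfc_sd SD of the per-gene per-line single-agent log2 effects.
#' @param interaction_genes How many genes carry a planted interaction.
#' @param interaction_lfc Planted log2 deviation of the combination from
#'   additivity (negative = combination suppresses beyond additive).
#' @param dispersion NB dispersion.
#' @param libsize_factor_range Per-sample depth factors (uniform).
#' @param seed Optional integer seed.
#' @return List: `counts` (genes x samples), `samples` (`sample`, `line`,
#'   `condition`, `replicate`), `truth` (gene, interaction flag and size).
#' @export
simulate_synergy_pseudobulk <- function(n_genes = 2000, n_lines = 3,
                                        reps = 2, mean_log = log(100),
                                        mean_sd = 1, lfc_sd = 0.15,
                                        interaction_genes = 50,
                                        interaction_lfc = -1,
                                        dispersion = 0.05,
                                        libsize_factor_range = c(0.7, 1.4),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conditions <- c("vehicle", "A", "B", "AB")
  samples <- expand.grid(replicate = paste0("r", seq_len(reps)),
                         condition = conditions,
                         line = paste0("L", seq_len(n_lines)),
                         stringsAsFactors = FALSE)
  samples$sample <- with(samples, paste(line, condition, replicate, sep = "_"))
  ns <- nrow(samples)
  inter_idx <- sample.int(n_genes, interaction_genes)
  genes <- paste0("G", seq_len(n_genes))
  counts <- matrix(0L, n_genes, ns, dimnames = list(genes, samples$sample))
  sf <- stats::runif(ns, libsize_factor_range[1], libsize_factor_range[2])
  for (l in unique(samples$line)) {
    base <- stats::rlnorm(n_genes, mean_log, mean_sd)
    bA <- stats::rnorm(n_genes, 0, lfc_sd)
    bB <- stats::rnorm(n_genes, 0, lfc_sd)
    delta <- numeric(n_genes)
    delta[inter_idx] <- interaction_lfc
    for (j in which(samples$line == l)) {
      lfc <- switch(samples$condition[j],
                    vehicle = 0, A = bA, B = bB, AB = bA + bB + delta)
      mu <- base * 2^lfc * sf[j]
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
  }
  list(counts = counts, samples = samples[, c("sample", "line", "condition",
                                              "replicate")],
       truth = data.frame(gene = genes,
                          interaction = seq_len(n_genes) %in% inter_idx,
                          interaction_lfc = ifelse(
                            seq_len(n_genes) %in% inter_idx,
                            interaction_lfc, 0),
                          stringsAsFactors = FALSE))
}
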