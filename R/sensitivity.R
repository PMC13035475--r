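# Drug-sensitivity phenotypes from demultiplexed pool representation.

#' Exponential growth rate from two cell counts
#'
#' `r = ln(Yt / Y0) / t`, in units of 1/t (per hour when t is in hours).
#'
#' @param y0,yt Cell counts at time 0 and t (both positive).
#' @param t Elapsed time (positive).
#' @return The growth rate r.
#' @export
growth_rate <- function(y0, yt, t) {
  if (any(y0 <= 0) || any(yt <= 0) || any(t <= 0))
    stop("y0, yt and t must be positive")
  log(yt / y0) / t
}

#' Pool-balancing seed counts inverse to growth rate
#'
#' Fast-growing lines must be seeded low for every line to remain
#' represented after days of growth. The default mode seeds proportionally
#' to `exp(-r * horizon)`, which equalizes expected representation at the
#' horizon; the literal mode seeds proportionally to `1/r` (all rates must
#' then be positive). Counts are rounded by largest remainder so they sum
#' exactly to `total`.
#'
#' @param rates Named growth rates (per hour).
#' @param total Total cells to seed.
#' @param horizon Growth horizon in hours (default-mode only).
#' @param mode `"horizon"` (default) or `"literal"` (1/r).
#' @return Integer seed counts summing to `total`.
#' @export
balance_seeding <- function(rates, total, horizon = 72,
                            mode = c("horizon", "literal")) {
  mode <- match.arg(mode)
  if (any(!is.finite(rates))) stop("rates must be finite")
  if (total <= 0) stop("total must be positive")
  w <- if (mode == "horizon") {
    exp(-rates * horizon)
  } else {
    if (any(rates <= 0)) stop("literal 1/r mode requires all rates > 0")
    1 / rates
  }
  raw <- w / sum(w) * total
  seeds <- floor(raw)
  rem <- total - sum(seeds)
  if (rem > 0) {
    extra <- order(raw - seeds, decreasing = TRUE)[seq_len(rem)]
    seeds[extra] <- seeds[extra] + 1
  }
  stats::setNames(as.integer(seeds), names(rates))
}

# counts -> fractions per (line, condition, replicate); pseudocount 0.5 on
# zero cells keeps downstream ratios/logs defined (Haldane-Anscombe)
.pool_fractions <- function(cell_meta, pseudocount = 0.5) {
  cm <- cell_meta
  cm <- cm[!(cm$line_id %in% c("unassigned", "doublet")), , drop = FALSE]
  lines <- sort(unique(cm$line_id))
  key <- interaction(cm$condition, cm$dose, cm$replicate, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- cm[key == k, , drop = FALSE]
    n <- table(factor(sub$line_id, levels = lines))
    n_adj <- ifelse(n == 0, pseudocount, as.numeric(n))
    data.frame(line = lines, condition = sub$condition[1L],
               dose = sub$dose[1L], replicate = sub$replicate[1L],
               n_cells = as.integer(n),
               pool_fraction = n_adj / sum(n_adj),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-line pool representation across conditions
#'
#' Tabulates assigned cells per line within each sample and derives
#' fractions (pseudocount 0.5 on zero counts), the display-style relative
#' representation (counts normalized by the maximum per-line count within
#' each condition) and, when a vehicle condition is present, the ratio of
#' each line's fraction to its vehicle fraction (replicate fractions are
#' averaged before the ratio).
#'
#' @param cell_meta `cell_meta` of a [pooled_experiment()] or any
#'   data.frame with `line_id`, `condition`, `dose`, `replicate`.
#'   Unassigned/doublet cells are dropped.
#' @param vehicle Vehicle condition label.
#' @return `data.frame` of class `sensitivity_table`: per line x condition
#'   x dose x replicate rows with `n_cells`, `pool_fraction`,
#'   `relative_representation`, plus per line x condition `ratio_vs_vehicle`.
#' @export
relative_representation <- function(cell_meta, vehicle = "DMSO") {
  tab <- .pool_fractions(cell_meta)
  if (!vehicle %in% tab$condition)
    stop("vehicle condition '", vehicle, "' absent")
  tab$relative_representation <- stats::ave(
    as.numeric(tab$n_cells), paste(tab$condition, tab$dose),
    FUN = function(v) v / max(v))
  # replicate-averaged fractions per line x condition x dose
  agg <- stats::aggregate(pool_fraction ~ line + condition + dose, tab, mean)
  veh <- agg[agg$condition == vehicle, c("line", "pool_fraction")]
  names(veh)[2L] <- "vehicle_fraction"
  agg <- merge(agg, veh, by = "line", sort = FALSE)
  agg$ratio_vs_vehicle <- agg$pool_fraction / agg$vehicle_fraction
  tab <- merge(tab, agg[, c("line", "condition", "dose", "ratio_vs_vehicle")],
               by = c("line", "condition", "dose"), sort = FALSE)
  tab <- tab[order(tab$condition, tab$dose, tab$replicate, tab$line), ]
  rownames(tab) <- NULL
  class(tab) <- c("sensitivity_table", "data.frame")
  tab
}

#' Per-line and per-group relative survival
#'
#' Relative survival of a line is the log2 ratio of its (pseudocounted)
#' pool fraction under drug to its fraction under vehicle; 0 means no
#' depletion, -2 a four-fold depletion. Replicate-level scores give the
#' reported mean and SD; mutation-group scores average member lines.
#'
#' @param cell_meta As in [relative_representation()].
#' @param condition Drug condition to score.
#' @param vehicle Vehicle condition label.
#' @param groups Optional named list of line-id vectors (e.g. mutation
#'   groups); empty groups raise an error.
#' @return List with `lines` (`line`, `score`, `score_sd`, per-replicate
#'   scores averaged) and `groups` (`group`, `score`, `n_lines`).
#' @export
relative_survival <- function(cell_meta, condition, vehicle = "DMSO",
                              groups = NULL) {
  tab <- .pool_fractions(cell_meta)
  if (!condition %in% tab$condition) stop("condition absent: ", condition)
  if (!vehicle %in% tab$condition) stop("vehicle absent: ", vehicle)
  drug <- tab[tab$condition == condition, , drop = FALSE]
  veh <- tab[tab$condition == vehicle, , drop = FALSE]
  veh_f <- tapply(veh$pool_fraction, veh$line, mean)
  # per-replicate score against the replicate-averaged vehicle fraction
  drug$score <- log2(drug$pool_fraction / veh_f[drug$line])
  per_line <- do.call(rbind, lapply(split(drug, drug$line), function(d) {
    data.frame(line = d$line[1L], score = mean(d$score),
               score_sd = if (nrow(d) > 1L) stats::sd(d$score) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_line) <- NULL
  group_tab <- NULL
  if (!is.null(groups)) {
    group_tab <- do.call(rbind, lapply(names(groups), function(g) {
      members <- intersect(groups[[g]], per_line$line)
      if (!length(members)) stop("group '", g, "' has no member lines")
      data.frame(group = g,
                 score = mean(per_line$score[per_line$line %in% members]),
                 n_lines = length(members), stringsAsFactors = FALSE)
    }))
  }
  list(lines = per_line, groups = group_tab)
}

#' Log-log dose-response slope of pool representation
#'
#' Per line, the OLS slope of log10(representation ratio vs vehicle) on
#' log10(dose) over the drug doses, with the one-sided Pearson-R p value in
#' the depletion direction (negative slope) by default. Replicates are
#' averaged into one point per dose before fitting.
#'
#' @param cell_meta As in [relative_representation()]; must contain >= 3
#'   distinct non-zero doses.
#' @param vehicle Vehicle condition label.
#' @param sided `"less"` (depletion, default), `"greater"` or `"two"`.
#' @return `data.frame`: `line`, `slope`, `r`, `p_value`, `n_doses`.
#' @export
dose_slope <- function(cell_meta, vehicle = "DMSO",
                       sided = c("less", "greater", "two")) {
  sided <- match.arg(sided)
  tab <- .pool_fractions(cell_meta)
  veh <- tab[tab$condition == vehicle, , drop = FALSE]
  if (!nrow(veh)) stop("vehicle absent: ", vehicle)
  veh_f <- tapply(veh$pool_fraction, veh$line, mean)
  drug <- tab[tab$condition != vehicle & tab$dose > 0, , drop = FALSE]
  agg <- stats::aggregate(pool_fraction ~ line + dose, drug, mean)
  agg$ratio <- agg$pool_fraction / veh_f[agg$line]
  if (any(agg$ratio <= 0)) stop("nonpositive representation ratio")
  out <- lapply(split(agg, agg$line), function(d) {
    if (nrow(d) < 3L) stop("line ", d$line[1L], ": need >= 3 doses")
    x <- log10(d$dose)
    y <- log10(d$ratio)
    slope <- stats::cov(x, y) / stats::var(x)
    r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
    n <- nrow(d)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- switch(sided,
                two = 2 * stats::pt(-abs(tt), n - 2),
                greater = stats::pt(tt, n - 2, lower.tail = FALSE),
                less = stats::pt(tt, n - 2))
    data.frame(line = d$line[1L], slope = slope, r = r, p_value = p,
               n_doses = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mutation association by L1-penalized regression
#'
#' Regresses per-line relative-survival scores on the binary mutation
#' incidence matrix with an L1 penalty; the penalty is chosen by
#' leave-one-out cross-validation. Mutations present in fewer than
#' `min_carriers` lines are dropped (singletons are unidentifiable in
#' small pools). Negative coefficients mark sensitizing mutations.
#'
#' @param mm A [mutation_matrix()] (lines x mutations).
#' @param scores Named per-line survival scores (names = line ids).
#' @param min_carriers Minimum carrier lines for a covariate.
#' @param lambda Optional penalty grid passed to glmnet.
#' @return `data.frame` of selected `mutation`, `coefficient`; empty (with
#'   a warning) when the response is constant.
#' @export
mutation_lasso <- function(mm, scores, min_carriers = 2L, lambda = NULL) {
  lines <- intersect(rownames(mm), names(scores))
  if (length(lines) < 5L) stop("need >= 5 lines with both mutations and scores")
  x <- unclass(mm)[lines, , drop = FALSE]
  y <- scores[lines]
  if (any(!is.finite(y))) stop("scores must be finite")
  keep <- colSums(x) >= min_carriers & colSums(x) <= length(lines) - 1L
  x <- x[, keep, drop = FALSE]
  if (stats::sd(y) == 0) {
    warning("constant response; no mutation selected")
    return(data.frame(mutation = character(0), coefficient = numeric(0)))
  }
  if (ncol(x) < 2L) stop("need >= 2 informative mutation covariates")
  cv <- glmnet::cv.glmnet(x, y, nfolds = length(y), grouped = FALSE,
                          lambda = lambda, standardize = TRUE)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
  sel <- beta != 0
  data.frame(mutation = names(beta)[sel], coefficient = unname(beta[sel]),
             stringsAsFactors = FALSE)
}
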