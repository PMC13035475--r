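# Core domain containers shared by every pipeline stage.

#' Construct a pooled single-cell experiment
#'
#' The central container of the package: a sparse cells-by-genes UMI count
#' matrix plus per-cell and per-gene annotation for a pooled multi-cell-line
#' drug-response experiment (many lines mixed in one culture/xenograft,
#' hashed samples, vehicle and drug arms at one or more doses).
#'
#' @param counts Non-negative integer matrix (base or `Matrix` sparse),
#'   cells in rows, genes in columns. Stored as `dgCMatrix`.
#' @param cell_meta `data.frame` with one row per cell. Must contain
#'   `barcode` (unique). Missing columns among `line_id`, `condition`,
#'   `dose`, `replicate`, `hash_id`, `doublet_flag`, `apoptotic_flag`,
#'   `phase` are filled with defaults (`"unassigned"`, vehicle condition,
#'   dose 0, `"r1"`, flags `FALSE`, phase `"unset"`).
#' @param gene_meta Optional `data.frame` with one row per gene: `symbol`,
#'   `is_mito_encoded`, `is_mito_resident`. When omitted, symbols are taken
#'   from `colnames(counts)` and mitochondrially encoded genes are derived
#'   from the symbol prefix (see [is_mito_symbol()]).
#' @param genesets Named list of character vectors of gene symbols (e.g.
#'   cell-cycle sets, expression programs). Every set must be non-empty.
#' @param vehicle_labels Condition labels treated as vehicle/DMSO; cells in
#'   these conditions must have `dose == 0` and vice versa.
#'
#' @return An object of class `pooled_experiment`: a list with elements
#'   `counts`, `cell_meta`, `gene_meta`, `genesets`, `vehicle_labels`.
#' @export
pooled_experiment <- function(counts, cell_meta, gene_meta = NULL,
                              genesets = list(),
                              vehicle_labels = c("DMSO", "vehicle")) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers (UMIs)")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (is.null(cell_meta$barcode)) stop("cell_meta must contain a 'barcode' column")
  cell_meta$barcode <- as.character(cell_meta$barcode)
  if (anyDuplicated(cell_meta$barcode)) stop("cell barcodes must be unique")
  if (nrow(cell_meta) != nrow(counts))
    stop("cell_meta rows (", nrow(cell_meta), ") != matrix cells (", nrow(counts), ")")

  defaults <- list(line_id = "unassigned", condition = vehicle_labels[[1L]],
                   dose = 0, replicate = "r1", hash_id = "unassigned",
                   doublet_flag = FALSE, apoptotic_flag = FALSE, phase = "unset")
  for (nm in names(defaults)) {
    if (is.null(cell_meta[[nm]])) cell_meta[[nm]] <- defaults[[nm]]
  }
  cell_meta$dose <- as.numeric(cell_meta$dose)
  if (any(cell_meta$dose < 0)) stop("dose must be non-negative")
  is_veh <- cell_meta$condition %in% vehicle_labels
  if (any(is_veh & cell_meta$dose != 0))
    stop("vehicle-condition cells must have dose 0")
  if (any(!is_veh & cell_meta$dose == 0))
    stop("non-vehicle cells must have dose > 0")

  if (is.null(gene_meta)) {
    symbol <- colnames(counts)
    if (is.null(symbol)) symbol <- paste0("G", seq_len(ncol(counts)))
    gene_meta <- data.frame(symbol = symbol,
                            is_mito_encoded = is_mito_symbol(symbol),
                            is_mito_resident = FALSE,
                            stringsAsFactors = FALSE)
  } else {
    gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
    if (is.null(gene_meta$symbol)) stop("gene_meta must contain 'symbol'")
    if (is.null(gene_meta$is_mito_encoded))
      gene_meta$is_mito_encoded <- is_mito_symbol(gene_meta$symbol)
    if (is.null(gene_meta$is_mito_resident)) gene_meta$is_mito_resident <- FALSE
  }
  if (nrow(gene_meta) != ncol(counts))
    stop("gene_meta rows (", nrow(gene_meta), ") != matrix genes (", ncol(counts), ")")
  colnames(counts) <- gene_meta$symbol
  rownames(counts) <- cell_meta$barcode

  if (length(genesets)) {
    if (is.null(names(genesets)) || any(!nzchar(names(genesets))))
      stop("genesets must be a named list")
    empty <- lengths(genesets) == 0L
    if (any(empty))
      stop("empty geneset(s): ", paste(names(genesets)[empty], collapse = ", "))
  }

  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, genesets = genesets,
                 vehicle_labels = vehicle_labels),
            class = "pooled_experiment")
}

#' @export
print.pooled_experiment <- function(x, ...) {
  cat("pooled_experiment: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes\n", sep = "")
  cat("  lines:      ", paste(sort(unique(x$cell_meta$line_id)), collapse = ", "), "\n")
  cat("  conditions: ", paste(sort(unique(x$cell_meta$condition)), collapse = ", "), "\n")
  if (length(x$genesets))
    cat("  genesets:   ", paste(names(x$genesets), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.pooled_experiment <- function(x) dim(x$counts)

#' Subset a pooled experiment by cells
#'
#' @param exp A [pooled_experiment()].
#' @param cells Logical, integer or barcode-character index over cells.
#' @return A `pooled_experiment` restricted to the selected cells.
#' @export
subset_cells <- function(exp, cells) {
  stopifnot(inherits(exp, "pooled_experiment"))
  if (is.character(cells)) cells <- match(cells, exp$cell_meta$barcode)
  exp$counts <- exp$counts[cells, , drop = FALSE]
  exp$cell_meta <- exp$cell_meta[cells, , drop = FALSE]
  rownames(exp$cell_meta) <- NULL
  exp
}

#' Mitochondrially encoded gene predicate
#'
#' Genes encoded on the mitochondrial genome are identified by the
#' conventional human symbol prefix `MT-` (case-insensitive). An explicit
#' annotation table passed to [pooled_experiment()] overrides this rule.
#'
#' @param symbol Character vector of gene symbols.
#' @return Logical vector.
#' @export
is_mito_symbol <- function(symbol) {
  grepl("^MT-", toupper(symbol))
}

#' QC thresholds for apoptotic-cell flagging
#'
#' Cells under drug pressure that are dying show few detected genes, low
#' total UMI counts and a high share of mitochondrially encoded transcripts.
#' The defaults (fewer than 1,000 detected genes, fewer than 2,000 counts,
#' mitochondrial fraction above 0.15) are the conventional apoptotic
#' thresholds for droplet scRNA-seq.
#'
#' @param min_genes Minimum detected genes for a healthy cell.
#' @param min_counts Minimum total UMI counts.
#' @param max_mito_frac Maximum mitochondrially encoded count fraction.
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 1000L, min_counts = 2000L,
                          max_mito_frac = 0.15) {
  if (min_genes <= 0 || min_counts <= 0) stop("thresholds must be positive")
  if (max_mito_frac <= 0 || max_mito_frac >= 1)
    stop("max_mito_frac must be in (0, 1)")
  structure(list(min_genes = as.integer(min_genes),
                 min_counts = as.integer(min_counts),
                 max_mito_frac = max_mito_frac),
            class = "qc_thresholds")
}

#' Per-line genotype reference
#'
#' Alt-allele dosages of each cell line at a panel of biallelic SNPs, the
#' ground truth against which cells and pseudobulk clusters are genotyped.
#' Dosage is 0 (hom ref), 0.5 (het), 1 (hom alt) or `NA` (uncalled).
#'
#' @param dosage Numeric matrix, lines in rows, variants in columns; values
#'   in {0, 0.5, 1, NA}.
#' @param line_ids,variant_ids Row/column identifiers; variant ids are
#'   `chrom:pos:ref:alt` strings and must be unique.
#' @return Object of class `genotype_reference`.
#' @export
genotype_reference <- function(dosage, line_ids = rownames(dosage),
                               variant_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(line_ids) || is.null(variant_ids))
    stop("line_ids and variant_ids are required")
  if (nrow(dosage) < 2L) stop("need at least 2 lines")
  if (ncol(dosage) < 1L) stop("need at least 1 variant")
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids")
  ok <- is.na(dosage) | dosage %in% c(0, 0.5, 1)
  if (!all(ok)) stop("dosage values must be 0, 0.5, 1 or NA")
  dimnames(dosage) <- list(line_ids, variant_ids)
  structure(list(dosage = dosage,
                 line_ids = as.character(line_ids),
                 variant_ids = as.character(variant_ids)),
            class = "genotype_reference")
}

#' @export
print.genotype_reference <- function(x, ...) {
  cat("genotype_reference: ", length(x$line_ids), " lines x ",
      length(x$variant_ids), " variants (",
      sum(is.na(x$dosage)), " uncalled)\n", sep = "")
  invisible(x)
}

#' Per-cell allele counts
#'
#' Long-format ref/alt read counts per (barcode, variant); the evidence
#' consumed by genotype demultiplexing.
#'
#' @param df `data.frame` with columns `barcode`, `variant_id`, `ref_reads`,
#'   `alt_reads` (non-negative integers).
#' @param reference Optional [genotype_reference()]; when given, every
#'   `variant_id` must exist in it.
#' @return The validated `data.frame` with class `allele_counts`.
#' @export
allele_counts <- function(df, reference = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("barcode", "variant_id", "ref_reads", "alt_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$ref_reads < 0) || any(df$alt_reads < 0))
    stop("read counts must be non-negative")
  if (!is.null(reference)) {
    unknown <- setdiff(unique(df$variant_id), reference$variant_ids)
    if (length(unknown))
      stop(length(unknown), " variant(s) absent from the genotype reference")
  }
  class(df) <- c("allele_counts", "data.frame")
  df
}

#' Binary mutation incidence matrix
#'
#' Lines-by-mutations indicator matrix (e.g. `KRAS_G12C`, `BRAF_V600E`)
#' used as covariates for sensitivity association.
#'
#' @param m Matrix of 0/1 indicators with line ids as rownames and mutation
#'   names as colnames.
#' @return Object of class `mutation_matrix` (a base matrix).
#' @export
mutation_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("mutation matrix needs line rownames and mutation colnames")
  if (!all(m %in% c(0, 1))) stop("mutation matrix must be binary")
  storage.mode(m) <- "numeric"
  class(m) <- c("mutation_matrix", class(m))
  m
}
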