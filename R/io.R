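# Readers/writers for the standard formats the pipeline touches.

#' Read a per-line genotype reference from VCF
#'
#' Parses a multi-sample VCF (one sample column per cell line) into a
#' [genotype_reference()]. Genotypes `0/0`, `0/1`, `1/1` map to dosages 0,
#' 0.5, 1; uncalled (`./.`) maps to `NA` and is excluded from likelihoods
#' downstream. Multiallelic records and indels are skipped with a warning:
#' the assignment model consumes biallelic SNPs only.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [genotype_reference()].
#' @export
read_genotype_reference <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has zero sample columns")
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!keep))
    warning(sum(!keep), " multiallelic/indel record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  variant_ids <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  if (anyDuplicated(variant_ids)) stop("duplicate variant id in VCF")
  # tolerate phased separators; anything beyond {0/0,0/1,1/0,1/1,./.} errors
  gt_chr <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = 0, "0/1" = 0.5, "1/0" = 0.5, "1/1" = 1, "./." = NA_real_)
  bad <- !is.na(gt_chr) & !(gt_chr %in% names(map))
  if (any(bad))
    stop("unrecognized genotype string(s): ",
         paste(unique(gt_chr[bad]), collapse = ", "))
  dosage <- matrix(map[gt_chr], nrow = nrow(gt_chr), ncol = ncol(gt_chr))
  genotype_reference(t(dosage), line_ids = colnames(gt),
                     variant_ids = variant_ids)
}

#' Read a pooled experiment from MatrixMarket triplet files
#'
#' Reads the conventional triplet trio (matrix.mtx + barcodes + features)
#' and optional per-cell metadata into a [pooled_experiment()].
#'
#' @param matrix_path MatrixMarket triplet file of UMI counts.
#' @param barcodes_path One barcode per line.
#' @param features_path One gene symbol per line (first tab-separated field
#'   is used, so 10x-style `id<TAB>symbol<TAB>type` files work).
#' @param cell_meta_path Optional CSV keyed by `barcode`.
#' @param orientation `"cells_in_columns"` (the common triplet convention;
#'   default) or `"cells_in_rows"`.
#' @param gene_meta Optional gene annotation `data.frame` overriding the
#'   symbol-prefix mitochondrial rule.
#' @param ... Passed to [pooled_experiment()].
#' @return A [pooled_experiment()].
#' @export
read_counts <- function(matrix_path, barcodes_path, features_path,
                        cell_meta_path = NULL,
                        orientation = c("cells_in_columns", "cells_in_rows"),
                        gene_meta = NULL, ...) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(matrix_path)
  if (orientation == "cells_in_columns") m <- Matrix::t(m)
  barcodes <- readLines(barcodes_path)
  features <- vapply(strsplit(readLines(features_path), "\t", fixed = TRUE),
                     `[[`, character(1), 1L)
  if (length(barcodes) != nrow(m))
    stop("barcode list length (", length(barcodes),
         ") != matrix cells (", nrow(m), ")")
  if (length(features) != ncol(m))
    stop("feature list length (", length(features),
         ") != matrix genes (", ncol(m), ")")
  cell_meta <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  if (!is.null(cell_meta_path)) {
    extra <- utils::read.csv(cell_meta_path, stringsAsFactors = FALSE)
    if (is.null(extra$barcode)) stop("cell metadata CSV must have 'barcode'")
    cell_meta <- merge(cell_meta, extra, by = "barcode", all.x = TRUE,
                       sort = FALSE)
    cell_meta <- cell_meta[match(barcodes, cell_meta$barcode), , drop = FALSE]
  }
  colnames(m) <- features
  pooled_experiment(m, cell_meta, gene_meta = gene_meta, ...)
}

#' Write stage outputs as plain-text tables
#'
#' Writes each element of a named list of data frames as a tab-separated
#' file `<name>.tsv` with a header row. Output is bit-identical given
#' identical inputs; an empty table yields a header-only file.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_results_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(as.data.frame(tables[[nm]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
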