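#' @importFrom methods as is new
#' @importFrom Matrix colSums rowSums rowMeans colMeans t sparseMatrix Diagonal readMM writeMM
NULL

# Gene symbols whose historical spellings differ from the HGNC symbol used
# throughout the package. Applied after upper-casing.
.gene_aliases <- c("MLAN-A" = "MLANA", "MLAN.A" = "MLANA")

#' Normalise gene symbols
#'
#' Upper-cases symbols, maps known aliases (e.g. `Mlan-A` to `MLANA`) and
#' disambiguates duplicates by suffixing `_2`, `_3`, ... in order of
#' appearance.
#'
#' @param ids character vector of gene symbols.
#' @return character vector of unique, upper-case symbols, same length.
#' @export
normalize_gene_ids <- function(ids) {
  ids <- toupper(trimws(as.character(ids)))
  hit <- ids %in% names(.gene_aliases)
  ids[hit] <- .gene_aliases[ids[hit]]
  dup <- duplicated(ids)
  if (any(dup)) {
    counts <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids[dup] <- paste0(ids[dup], "_", counts[dup])
  }
  ids
}

#' Cell-by-gene UMI count matrix
#'
#' The basic container of the pipeline: an integer count matrix with genes as
#' rows and cells as columns, plus the total number of genes probed by the
#' assay. The probed-gene count is the denominator of the mean gene count
#' (MGC) per cell, so it is carried alongside the matrix even when fewer
#' rows are present.
#'
#' @param counts non-negative integer matrix (genes x cells); base or
#'   `Matrix` sparse matrix.
#' @param gene_ids character vector of gene symbols, one per row; made
#'   unique via [normalize_gene_ids()] upstream.
#' @param cell_ids character vector of cell barcodes, one per column.
#' @param probed_gene_count total number of genes probed by the assay
#'   (e.g. 33531 for the 10x human reference); must be at least `nrow(counts)`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, probed_gene_count) {
  stopifnot(nrow(counts) == length(gene_ids),
            ncol(counts) == length(cell_ids))
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("empty count matrix")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (min(counts) < 0) stop("counts must be non-negative")
  probed_gene_count <- as.integer(probed_gene_count)
  if (probed_gene_count < nrow(counts))
    stop("probed_gene_count (", probed_gene_count,
         ") smaller than the number of gene rows (", nrow(counts), ")")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts,
                 gene_ids = gene_ids,
                 cell_ids = cell_ids,
                 probed_gene_count = probed_gene_count),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      "probed genes:", x$probed_gene_count, "\n")
  invisible(x)
}

#' Unit-MGC normalised expression matrix
#'
#' Holds per-cell scaled expression in arbitrary units (A.U.) such that every
#' cell's mean count per probed gene equals 1, i.e. every column sums to
#' `probed_gene_count`.
#'
#' @param values non-negative real matrix (genes x kept cells).
#' @param gene_ids,cell_ids row/column identifiers.
#' @param probed_gene_count the assay's probed-gene count (normalisation
#'   denominator).
#' @param sample_label label(s) for the sample of origin; either a single
#'   string or one label per cell.
#' @return object of class `norm_matrix`.
#' @export
norm_matrix <- function(values, gene_ids, cell_ids, probed_gene_count,
                        sample_label = "sample") {
  stopifnot(nrow(values) == length(gene_ids),
            ncol(values) == length(cell_ids))
  if (length(sample_label) == 1L)
    sample_label <- rep(sample_label, length(cell_ids))
  stopifnot(length(sample_label) == length(cell_ids))
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values,
                 gene_ids = gene_ids,
                 cell_ids = cell_ids,
                 probed_gene_count = as.integer(probed_gene_count),
                 sample_label = sample_label),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix:", nrow(x$values), "genes x", ncol(x$values), "cells",
      "(unit-MGC A.U.); samples:",
      paste(unique(x$sample_label), collapse = ", "), "\n")
  invisible(x)
}

# Extract one gene's values as a plain numeric vector.
gene_values <- function(nm, gene) {
  i <- match(gene, nm$gene_ids)
  if (is.na(i)) stop("gene not present: ", gene)
  as.numeric(nm$values[i, ])
}
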