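#' Read a genes-x-cells count matrix from CSV
#'
#' Reads the CSV dialect exported from a 10x feature-barcode matrix: a header
#' row of cell barcodes, then one row per gene with the gene symbol in the
#' first field and integer UMI counts in the remaining fields. Gene symbols
#' are upper-cased and de-duplicated (see [normalize_gene_ids()]); row order
#' is preserved.
#'
#' @param path path to the CSV file.
#' @param probed_gene_count total number of genes probed by the assay.
#' @return a [count_matrix()].
#' @export
read_counts_csv <- function(path, probed_gene_count) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty matrix in ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1L]]
  n_cells <- length(header) - 1L
  if (n_cells < 1L) stop("empty matrix in ", path, ": no cell columns")
  body <- fields[-1L]
  bad <- which(lengths(body) != n_cells + 1L)
  if (length(bad))
    stop("ragged row in ", path, " at line ", bad[1L] + 1L, ": expected ",
         n_cells + 1L, " fields, got ", lengths(body)[bad[1L]])
  gene_raw <- vapply(body, `[[`, character(1L), 1L)
  flat <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  bad <- which(is.na(vals) | vals != floor(vals) | vals < 0)
  if (length(bad)) {
    line <- (bad[1L] - 1L) %/% n_cells + 2L
    stop("non-integer count in ", path, " at line ", line,
         ": '", flat[bad[1L]], "'")
  }
  counts <- matrix(vals, nrow = length(body), ncol = n_cells, byrow = TRUE)
  count_matrix(as(as(counts, "generalMatrix"), "CsparseMatrix"),
               gene_ids = normalize_gene_ids(gene_raw),
               cell_ids = header[-1L],
               probed_gene_count = probed_gene_count)
}

#' Read a count matrix in MatrixMarket (10x) layout
#'
#' Expects a directory containing `matrix.mtx` plus the two sidecar tables
#' `features.tsv` (or `genes.tsv`; symbol in the second column when present)
#' and `barcodes.tsv`. Produces a [count_matrix()] equivalent to
#' [read_counts_csv()] on the same data.
#'
#' @param dir directory containing the three files.
#' @param probed_gene_count total number of genes probed by the assay.
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(dir, probed_gene_count) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dir, "genes.tsv")
  barc <- file.path(dir, "barcodes.tsv")
  if (!file.exists(mtx)) stop("missing matrix.mtx in ", dir)
  if (!file.exists(feat)) stop("missing features.tsv/genes.tsv sidecar in ", dir)
  if (!file.exists(barc)) stop("missing barcodes.tsv sidecar in ", dir)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file ", mtx,
                                         ": ", conditionMessage(e)))
  ftab <- utils::read.table(feat, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
  genes <- if (ncol(ftab) >= 2L) ftab[[2L]] else ftab[[1L]]
  cells <- readLines(barc)
  if (nrow(m) != length(genes))
    stop("feature sidecar has ", length(genes), " rows but matrix declares ",
         nrow(m))
  if (ncol(m) != length(cells))
    stop("barcode sidecar has ", length(cells), " rows but matrix declares ",
         ncol(m))
  count_matrix(as(m, "CsparseMatrix"),
               gene_ids = normalize_gene_ids(genes),
               cell_ids = cells,
               probed_gene_count = probed_gene_count)
}

#' Marker panel for non-epithelial cell purging
#'
#' Named marker sets used by [flag_cells()]. A cell is flagged for a lineage
#' if *any* marker of that lineage reaches `detection_threshold` counts
#' ("and/or" semantics); the remaining cells must express at least one
#' required epithelial marker to be kept. Blood and Langerhans panels default
#' to empty because no canonical list is fixed; supply them per dataset.
#'
#' @param melanocyte,langerhans,blood,conjunctival marker symbol vectors.
#' @param epithelial_required symbols of which at least one must be expressed.
#' @param detection_threshold minimum UMI count (>= 1) for "expressed".
#' @return object of class `marker_panel`.
#' @export
marker_panel <- function(melanocyte = c("DCT", "TYR", "TYRP1", "MLANA"),
                         langerhans = character(),
                         blood = character(),
                         conjunctival = "AQP5",
                         epithelial_required = c("KRT5", "KRT14", "KRT12"),
                         detection_threshold = 1) {
  if (detection_threshold < 1) stop("detection_threshold must be >= 1")
  if (length(epithelial_required) == 0L)
    stop("epithelial_required set must be non-empty")
  structure(list(melanocyte = toupper(melanocyte),
                 langerhans = toupper(langerhans),
                 blood = toupper(blood),
                 conjunctival = toupper(conjunctival),
                 epithelial_required = toupper(epithelial_required),
                 detection_threshold = detection_threshold),
            class = "marker_panel")
}

# TRUE per cell if any of `set` reaches the detection threshold.
.any_marker <- function(cm, set, thr, warn_label) {
  present <- intersect(set, cm$gene_ids)
  missing <- setdiff(set, cm$gene_ids)
  if (length(missing))
    warning("markers not found (", warn_label, "): ",
            paste(missing, collapse = ", "))
  if (length(present) == 0L) return(rep(FALSE, ncol(cm$counts)))
  sub <- cm$counts[present, , drop = FALSE]
  as.vector(Matrix::colSums(sub >= thr)) > 0
}

#' Flag non-epithelial cells by marker expression
#'
#' Assigns each cell exactly one flag. Priority order: melanocyte >
#' langerhans > blood > conjunctival; cells expressing a melanocyte marker
#' are purged even when they co-express epithelial keratins (such columns are
#' epithelial-melanocyte duplets). Cells passing all purge rules are flagged
#' `not_epithelial` unless at least one required epithelial marker is
#' expressed, otherwise `kept`.
#'
#' @param cm a [count_matrix()].
#' @param panel a [marker_panel()].
#' @return data.frame with columns `cell_id`, `flag`.
#' @export
flag_cells <- function(cm, panel = marker_panel()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(panel, "marker_panel"))
  thr <- panel$detection_threshold
  n <- ncol(cm$counts)
  flag <- rep("kept", n)
  epi <- .any_marker(cm, panel$epithelial_required, thr, "epithelial_required")
  flag[!epi] <- "not_epithelial"
  for (lineage in c("conjunctival", "blood", "langerhans", "melanocyte")) {
    set <- panel[[lineage]]
    if (length(set) == 0L) next
    hit <- .any_marker(cm, set, thr, lineage)
    flag[hit] <- lineage
  }
  data.frame(cell_id = cm$cell_ids, flag = flag, stringsAsFactors = FALSE)
}

#' Per-cell mean gene count (MGC)
#'
#' MGC of a cell is its total UMI count divided by the number of probed
#' genes (all assay rows, not only detected ones), so the scale is
#' comparable across samples of different depth. Also returns the
#' descending-sorted curve whose inflection (around 0.5 in the source data)
#' marks decaying cells.
#'
#' @param cm a [count_matrix()].
#' @return list with `mgc` (named per-cell vector) and `curve`
#'   (descending-sorted copy for plotting).
#' @export
compute_mgc <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$probed_gene_count <= 0) stop("probed_gene_count must be positive")
  mgc <- as.vector(Matrix::colSums(cm$counts)) / cm$probed_gene_count
  names(mgc) <- cm$cell_ids
  list(mgc = mgc, curve = sort(mgc, decreasing = TRUE))
}

#' Trim cells by mean gene count
#'
#' Restricts the analysis to cells with `low < MGC < high` (strict on both
#' ends: cells exactly at a bound are excluded). Only cells currently flagged
#' `kept` are considered; previously purged cells keep their flags.
#'
#' @param cm a [count_matrix()].
#' @param qc data.frame from [flag_cells()] (columns `cell_id`, `flag`).
#' @param low,high MGC bounds; defaults 0.5 and 2.5.
#' @return list with `cm` (trimmed [count_matrix()] of kept cells) and `qc`
#'   (data.frame `cell_id`, `mgc`, `flag` covering every input cell).
#' @export
trim_by_mgc <- function(cm, qc, low = 0.5, high = 2.5) {
  stopifnot(inherits(cm, "count_matrix"), low >= 0, low < high)
  stopifnot(identical(qc$cell_id, cm$cell_ids))
  mgc <- compute_mgc(cm)$mgc
  flag <- qc$flag
  was_kept <- flag == "kept"
  flag[was_kept & mgc <= low] <- "low_mgc"
  flag[was_kept & mgc >= high] <- "high_mgc"
  keep <- flag == "kept"
  if (!any(keep))
    stop("no cells survive the MGC trim (", low, ", ", high, ")")
  trimmed <- count_matrix(cm$counts[, keep, drop = FALSE],
                          gene_ids = cm$gene_ids,
                          cell_ids = cm$cell_ids[keep],
                          probed_gene_count = cm$probed_gene_count)
  list(cm = trimmed,
       qc = data.frame(cell_id = cm$cell_ids, mgc = unname(mgc), flag = flag,
                       stringsAsFactors = FALSE))
}

#' Normalise every cell to unit MGC
#'
#' Divides each column by its MGC so each cell's mean count per probed gene
#' equals 1 (equivalently, each column sums to `probed_gene_count`). The
#' resulting values are the arbitrary units (A.U.) used throughout the
#' analysis.
#'
#' @param cm a [count_matrix()] of kept cells.
#' @param sample_label sample name stored per cell.
#' @return a [norm_matrix()].
#' @export
normalize_to_unit_mgc <- function(cm, sample_label = "sample") {
  stopifnot(inherits(cm, "count_matrix"))
  mgc <- compute_mgc(cm)$mgc
  if (any(mgc == 0))
    stop("cell(s) with zero total count reached normalisation: ",
         paste(utils::head(cm$cell_ids[mgc == 0], 5L), collapse = ", "))
  values <- cm$counts %*% Matrix::Diagonal(x = 1 / mgc)
  norm_matrix(as(values, "CsparseMatrix"),
              gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
              probed_gene_count = cm$probed_gene_count,
              sample_label = sample_label)
}

# Percentage at fixed printed precision.
pct_of <- function(n, den, digits) {
  if (den == 0) return(0)
  round(100 * n / den, digits)
}

#' Per-sample cell accounting table
#'
#' Tabulates, per sample: total cells, each purge category (count and percent
#' of total, 2 decimals), the non-epithelial total and epithelial remainder
#' (percent of total, 1 decimal), cells within the MGC limits (percent of
#' epithelial, 1 decimal) and gauge-negative cells (percent of the MGC-kept
#' cells, 1 decimal; the denominator is stated in the `denominator` column).
#'
#' @param samples named list; each element is a list with `qc` (the full
#'   per-cell QC data.frame from [trim_by_mgc()]) and `cm` (the trimmed
#'   [count_matrix()] of kept cells).
#' @param gauge_gene symbol of the gauge gene (counts exactly 0 define the
#'   gauge-negative row).
#' @return long-format data.frame: `sample`, `category`, `n`, `pct`,
#'   `denominator`.
#' @export
accounting <- function(samples, gauge_gene = "KRT12") {
  stopifnot(length(samples) >= 1L)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be a named list")
  purge_cats <- c("melanocyte", "langerhans", "blood", "conjunctival",
                  "not_epithelial")
  out <- lapply(names(samples), function(s) {
    qc <- samples[[s]]$qc
    cm <- samples[[s]]$cm
    total <- nrow(qc)
    cat_n <- vapply(purge_cats, function(f) sum(qc$flag == f), integer(1L))
    non_epi <- sum(cat_n)
    epi <- total - non_epi
    kept <- sum(qc$flag == "kept")
    gz <- if (gauge_gene %in% cm$gene_ids)
      sum(cm$counts[gauge_gene, ] == 0) else NA_integer_
    data.frame(
      sample = s,
      category = c("total", purge_cats, "non_epithelial", "epithelial",
                   "mgc_kept", "gauge_zero"),
      n = c(total, cat_n, non_epi, epi, kept, gz),
      pct = c(100,
              vapply(cat_n, pct_of, numeric(1L), den = total, digits = 2),
              pct_of(non_epi, total, 1), pct_of(epi, total, 1),
              pct_of(kept, epi, 1),
              if (is.na(gz)) NA_real_ else pct_of(gz, kept, 1)),
      denominator = c("total", rep("total", length(purge_cats)), "total",
                      "total", "epithelial", "mgc_kept"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
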