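#' Select the analysis gene universe
#'
#' Ranks genes by overall expression (sum of normalised values over all kept
#' cells, descending) and keeps the top `top_n`. Ties are broken by symbol
#' order. Restricting tests to the strongly expressed genes avoids the
#' p-value degradation seen for sparsely detected genes.
#'
#' @param nm a [norm_matrix()].
#' @param top_n universe size (e.g. 6647); must not exceed the gene count.
#' @return object of class `gene_universe`: `genes` (ranked symbols),
#'   `totals`, `size`.
#' @export
select_gene_universe <- function(nm, top_n) {
  stopifnot(inherits(nm, "norm_matrix"))
  if (top_n <= 0) stop("top_n must be positive")
  if (top_n > length(nm$gene_ids))
    stop("top_n (", top_n, ") exceeds detected genes (",
         length(nm$gene_ids), ")")
  totals <- as.vector(Matrix::rowSums(nm$values))
  names(totals) <- nm$gene_ids
  o <- order(-totals, nm$gene_ids)
  structure(list(genes = nm$gene_ids[o][seq_len(top_n)],
                 totals = totals[o][seq_len(top_n)],
                 size = as.integer(top_n)),
            class = "gene_universe")
}

# Vectorised two-sided Welch t-test over matrix rows.
# Returns p-values; degenerate rows (zero pooled variance) get p = 1 when the
# means agree and p = 0 otherwise.
.welch_rows <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  stopifnot(nA >= 2L, nB >= 2L)
  mA <- as.vector(Matrix::rowMeans(A))
  mB <- as.vector(Matrix::rowMeans(B))
  vA <- (as.vector(Matrix::rowMeans(A * A)) - mA^2) * nA / (nA - 1)
  vB <- (as.vector(Matrix::rowMeans(B * B)) - mB^2) * nB / (nB - 1)
  vA <- pmax(vA, 0); vB <- pmax(vB, 0)
  se2 <- vA / nA + vB / nB
  tt <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  deg <- se2 == 0
  p[deg] <- ifelse(mA[deg] == mB[deg], 1, 0)
  list(p = p, mean_A = mA, mean_B = mB, t = tt, df = df)
}

#' Two-group test for a single gene
#'
#' Two-sided p-value comparing one gene's normalised expression between two
#' cell groups. Default is Welch's unequal-variance t-test; a Mann-Whitney
#' rank-sum alternative is available. When both groups are constant the
#' p-value is 1 if the means agree (no evidence of change) and 0 otherwise.
#'
#' @param values_A,values_B numeric expression vectors (>= 2 cells each).
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @return two-sided p-value.
#' @export
gene_test <- function(values_A, values_B,
                      method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  if (length(values_A) < 2L || length(values_B) < 2L)
    stop("both groups need at least 2 cells")
  if (method == "mann_whitney")
    return(stats::wilcox.test(values_A, values_B, exact = FALSE)$p.value)
  if (stats::var(values_A) == 0 && stats::var(values_B) == 0)
    return(if (mean(values_A) == mean(values_B)) 1 else 0)
  stats::t.test(values_A, values_B)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over the tested gene universe
#' (adjustment is per comparison, over exactly the genes tested there).
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values (BHp), same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Between-group expression ratio
#'
#' `R = mean(A) / mean(B)` of normalised expression, with its reciprocal.
#' When only `mean(B)` is zero the ratio is infinite and flagged for
#' exclusion from ranked tables; when both means are zero the ratio is
#' undefined.
#'
#' @param values_A,values_B numeric vectors (group expression values, or
#'   already-computed group means as length-1 vectors).
#' @return list with `R`, `inv_R`, `status`
#'   (`"ok"`, `"infinite"`, `"undefined"`).
#' @export
expression_ratio <- function(values_A, values_B) {
  mA <- mean(values_A); mB <- mean(values_B)
  if (mA == 0 && mB == 0)
    return(list(R = NA_real_, inv_R = NA_real_, status = "undefined"))
  if (mB == 0) return(list(R = Inf, inv_R = 0, status = "infinite"))
  if (mA == 0) return(list(R = 0, inv_R = Inf, status = "infinite"))
  list(R = mA / mB, inv_R = mB / mA, status = "ok")
}

#' Call differentially expressed genes
#'
#' Applies the DEG definition to a per-gene record table: a gene is a DEG
#' when its BH-adjusted p-value is below `alpha`; the gated call further
#' requires the expression ratio to exceed `rho` (downregulated, `R > rho`)
#' or its reciprocal to (`1/R > rho`, upregulated). "Down" means higher in
#' the less-differentiated group (group A of the comparison). Counts are
#' reported both ungated (BHp only, split by ratio direction) and gated; the
#' down/up ratio uses the ungated counts.
#'
#' @param records data.frame with at least `gene`, `R`, `BHp` (optionally
#'   `mean_A`, `mean_B`, `p`).
#' @param alpha BHp threshold (default 0.01).
#' @param rho ratio gate (default 1.35; the calibrated value whose
#'   reciprocal is 0.741).
#' @param comparison label stored on the result.
#' @return object of class `deg_table`: `records` (with `call` column),
#'   `counts`, `down_up_ratio`, `comparison`.
#' @export
call_degs <- function(records, alpha = 0.01, rho = 1.35, comparison = "") {
  stopifnot(is.data.frame(records), all(c("gene", "R", "BHp") %in%
                                          names(records)))
  if (rho < 1) stop("rho must be >= 1")
  sig <- !is.na(records$BHp) & records$BHp < alpha & !is.na(records$R)
  down_all <- sig & records$R > 1
  up_all <- sig & records$R < 1
  inv <- ifelse(is.na(records$R) | records$R == 0, NA, 1 / records$R)
  down_gated <- down_all & records$R > rho
  up_gated <- up_all & !is.na(inv) & inv > rho
  call <- rep("none", nrow(records))
  call[down_gated] <- "down"
  call[up_gated] <- "up"
  records$inv_R <- inv
  records$call <- call
  counts <- c(down_all = sum(down_all), up_all = sum(up_all),
              down_gated = sum(down_gated), up_gated = sum(up_gated))
  structure(list(records = records, counts = counts,
                 down_up_ratio = unname(counts["down_all"] / counts["up_all"]),
                 alpha = alpha, rho = rho, comparison = comparison),
            class = "deg_table")
}

#' @export
print.deg_table <- function(x, ...) {
  cat("deg_table", if (nzchar(x$comparison)) paste0("[", x$comparison, "]"),
      ": ", x$counts["down_all"], " down / ", x$counts["up_all"],
      " up (BHp < ", x$alpha, "); gated at ", x$rho, "x: ",
      x$counts["down_gated"], " / ", x$counts["up_gated"], "\n", sep = "")
  invisible(x)
}

#' Differential expression between two domain groups
#'
#' Runs the full per-gene pipeline for one comparison: Welch test over the
#' gene universe, BH adjustment within the comparison, ratio computation and
#' the DEG gate. Ranked top tables (default 60 genes per direction) are
#' sorted by descending R or 1/R — the ratio, not the BHp, carries the
#' biological ordering, since BHp is strongly driven by expression level.
#'
#' @param nm a [norm_matrix()] (typically the ordered, amalgamated sample).
#' @param groups a [build_comparison_groups()] result, or a list with a
#'   `pairs` element.
#' @param pair comparison label, e.g. `"D0-D1"`; must name an entry of
#'   `groups$pairs` or be `"A-B"` with `A`, `B` in `groups$groups`.
#' @param universe a [select_gene_universe()] result (or NULL for all genes).
#' @param alpha,rho DEG thresholds.
#' @param method test passed through to the per-gene test.
#' @param top_n ranked-table length per direction.
#' @return a `deg_table` with `top_down`/`top_up` views attached.
#' @export
compare_domains <- function(nm, groups, pair, universe = NULL,
                            alpha = 0.01, rho = 1.35,
                            method = c("welch_t", "mann_whitney"),
                            top_n = 60L) {
  method <- match.arg(method)
  stopifnot(inherits(nm, "norm_matrix"))
  pr <- if (!is.null(groups$pairs) && pair %in% names(groups$pairs)) {
    groups$pairs[[pair]]
  } else {
    nm2 <- strsplit(pair, "-", fixed = TRUE)[[1L]]
    if (length(nm2) != 2L || !all(nm2 %in% names(groups$groups)))
      stop("unknown comparison pair: ", pair)
    list(A = groups$groups[[nm2[1L]]], B = groups$groups[[nm2[2L]]])
  }
  if (length(pr$A) == 0L || length(pr$B) == 0L)
    stop("empty group in pair ", pair)
  if (length(intersect(pr$A, pr$B)))
    stop("groups overlap in pair ", pair)
  genes <- if (is.null(universe)) nm$gene_ids else universe$genes
  V <- nm$values[genes, , drop = FALSE]
  A <- V[, pr$A, drop = FALSE]
  B <- V[, pr$B, drop = FALSE]
  if (method == "welch_t") {
    w <- .welch_rows(A, B)
    p <- w$p; mA <- w$mean_A; mB <- w$mean_B
  } else {
    mA <- as.vector(Matrix::rowMeans(A))
    mB <- as.vector(Matrix::rowMeans(B))
    p <- vapply(seq_along(genes), function(i)
      stats::wilcox.test(as.numeric(A[i, ]), as.numeric(B[i, ]),
                         exact = FALSE)$p.value, numeric(1L))
  }
  R <- ifelse(mA == 0 & mB == 0, NA_real_,
              ifelse(mB == 0, Inf, mA / mB))
  records <- data.frame(gene = genes, mean_A = mA, mean_B = mB, R = R,
                        p = p, BHp = bh_adjust(p), stringsAsFactors = FALSE)
  dt <- call_degs(records, alpha = alpha, rho = rho, comparison = pair)
  dt$n_A <- length(pr$A)
  dt$n_B <- length(pr$B)
  rec <- dt$records
  rankable <- is.finite(rec$R) & !is.na(rec$BHp) & rec$BHp < alpha
  dn <- rec[rankable & rec$R > 1, ]
  up <- rec[rankable & rec$R < 1, ]
  dt$top_down <- utils::head(dn[order(-dn$R), ], top_n)
  dt$top_up <- utils::head(up[order(-up$inv_R), ], top_n)
  dt
}

#' Table-3-style summary of several comparisons
#'
#' @param deg_tables named list of `deg_table` objects.
#' @return data.frame: comparison, ungated and gated down/up counts, and the
#'   down/up ratio (2 decimals) from the ungated counts.
#' @export
deg_summary <- function(deg_tables) {
  do.call(rbind, lapply(names(deg_tables), function(nmx) {
    ct <- deg_tables[[nmx]]$counts
    data.frame(comparison = nmx,
               down_all = ct[["down_all"]], up_all = ct[["up_all"]],
               down_gated = ct[["down_gated"]], up_gated = ct[["up_gated"]],
               down_up_ratio = round(ct[["down_all"]] / ct[["up_all"]], 2),
               stringsAsFactors = FALSE)
  }))
}

#' Significant-gene yield by expression level
#'
#' Ranks all detected genes by overall expression (descending), bins them
#' into fixed-size quantiles and counts, per bin, the genes reaching
#' `BHp < alpha` in the given comparison (BH adjustment over the whole
#' examined set). The yield decays with decreasing expression because
#' sparsely detected genes carry little statistical power.
#'
#' @param nm a [norm_matrix()].
#' @param groups,pair as in [compare_domains()].
#' @param n_quantiles number of bins (default 9).
#' @param genes_per_quantile genes per bin (default 2000).
#' @param alpha BHp threshold.
#' @return data.frame `quantile`, `n_signif`, with attribute `total_signif`.
#' @export
bhp_yield_by_expression <- function(nm, groups, pair, n_quantiles = 9L,
                                    genes_per_quantile = 2000L,
                                    alpha = 0.01) {
  n_exam <- n_quantiles * genes_per_quantile
  if (n_exam > length(nm$gene_ids))
    stop("not enough detected genes (", length(nm$gene_ids), ") for ",
         n_quantiles, " x ", genes_per_quantile)
  uni <- select_gene_universe(nm, n_exam)
  dt <- compare_domains(nm, groups, pair, universe = uni, alpha = alpha)
  sig <- !is.na(dt$records$BHp) & dt$records$BHp < alpha
  bin <- rep(seq_len(n_quantiles), each = genes_per_quantile)
  out <- data.frame(quantile = seq_len(n_quantiles),
                    n_signif = as.integer(tapply(sig, bin, sum)))
  attr(out, "total_signif") <- sum(sig)
  out
}
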