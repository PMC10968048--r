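#' Classify gene trajectories across the ordered transitions
#'
#' Labels each universe gene by its behaviour over the informative
#' transitions (default D0-D1, D123-D4i.1, D4i.1-D4i.2):
#' `continuous_down`/`continuous_up` genes show a same-direction BHp call at
#' every transition; `d0d1_only_down`/`d0d1_only_up` genes show a call at
#' the first transition and no call in either direction afterwards; all
#' others are `other`. Continuity uses ungated (BHp-only) calls by default;
#' `gated` applies the ratio gate throughout. The gated sub-count at the
#' first transition (ratio beyond `rho`) is always reported via the
#' `d0d1_gate_passed` column.
#'
#' @param deg_tables list of `deg_table` objects in transition order (first
#'   must be the D0-D1 comparison); all over the same gene universe.
#' @param alpha BHp threshold.
#' @param rho ratio gate for the gated columns.
#' @param gated if TRUE, require the ratio gate at every transition for all
#'   labels.
#' @return data.frame: `gene`, `label`, `R_overall` (first-group mean over
#'   last-group mean), `inv_R_overall`, `R1` (first-transition ratio),
#'   `d0d1_gate_passed`; attribute `counts` tabulates the labels.
#' @export
classify_trajectory <- function(deg_tables, alpha = 0.01, rho = 1.35,
                                gated = FALSE) {
  stopifnot(length(deg_tables) >= 2L)
  genes <- deg_tables[[1L]]$records$gene
  for (dt in deg_tables[-1L])
    if (!identical(dt$records$gene, genes))
      stop("deg tables do not share one gene universe")
  k <- length(deg_tables)
  down <- up <- matrix(FALSE, length(genes), k)
  for (j in seq_len(k)) {
    rec <- deg_tables[[j]]$records
    sig <- !is.na(rec$BHp) & rec$BHp < alpha & !is.na(rec$R)
    dn <- sig & rec$R > 1
    upj <- sig & rec$R < 1
    if (gated) {
      dn <- dn & rec$R > rho
      upj <- upj & is.finite(rec$R) & rec$R > 0 & (1 / rec$R) > rho
    }
    down[, j] <- dn
    up[, j] <- upj
  }
  any_later <- (rowSums(down[, -1L, drop = FALSE]) +
                  rowSums(up[, -1L, drop = FALSE])) > 0
  label <- rep("other", length(genes))
  label[down[, 1L] & !any_later] <- "d0d1_only_down"
  label[up[, 1L] & !any_later] <- "d0d1_only_up"
  label[rowSums(down) == k] <- "continuous_down"
  label[rowSums(up) == k] <- "continuous_up"
  first <- deg_tables[[1L]]$records
  last <- deg_tables[[k]]$records
  mA <- first$mean_A
  mB <- last$mean_B
  R_over <- ifelse(mA == 0 & mB == 0, NA_real_,
                   ifelse(mB == 0, Inf, mA / mB))
  R1 <- first$R
  gate1 <- (!is.na(R1)) &
    (R1 > rho | (is.finite(R1) & R1 > 0 & (1 / R1) > rho))
  out <- data.frame(gene = genes, label = label, R_overall = R_over,
                    inv_R_overall = ifelse(is.finite(R_over) & R_over > 0,
                                           1 / R_over, NA_real_),
                    R1 = R1, d0d1_gate_passed = gate1,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(out$label,
                                      levels = c("continuous_down",
                                                 "continuous_up",
                                                 "d0d1_only_down",
                                                 "d0d1_only_up", "other")))
  out
}

#' Quantile profile of a gauge-ordered sample
#'
#' Splits the first `n_quantiles x cells_per_quantile` cells of the ordered
#' sample into consecutive equal bins and returns per-gene and gauge
#' per-bin mean expression. Tail cells beyond the binned range are dropped
#' (e.g. 4600 of 4700 cells in twenty 230-cell bins).
#'
#' @param os an [order_by_gauge()] result.
#' @param n_quantiles number of bins (default 20).
#' @param cells_per_quantile cells per bin; default
#'   `floor(n_cells / n_quantiles)`.
#' @param genes optional gene subset (defaults to all genes).
#' @param offset index of the first cell to bin (default 1; use the D4
#'   start index to profile within D4).
#' @return object of class `quantile_profile`: `profile` (genes x bins mean
#'   matrix), `gauge_means`, `n_quantiles`, `cells_per_quantile`, `offset`.
#' @export
quantile_profile <- function(os, n_quantiles = 20L, cells_per_quantile = NULL,
                             genes = NULL, offset = 1L) {
  stopifnot(inherits(os, "ordered_sample"))
  n_avail <- length(os$gauge_values) - offset + 1L
  if (is.null(cells_per_quantile))
    cells_per_quantile <- n_avail %/% n_quantiles
  need <- n_quantiles * cells_per_quantile
  if (need < n_quantiles || need > n_avail)
    stop("need ", need, " cells from offset ", offset, " but only ",
         n_avail, " available")
  use <- seq.int(offset, offset + need - 1L)
  if (is.null(genes)) genes <- os$matrix$gene_ids
  V <- os$matrix$values[genes, use, drop = FALSE]
  member <- Matrix::sparseMatrix(
    i = seq_len(need),
    j = rep(seq_len(n_quantiles), each = cells_per_quantile),
    x = 1 / cells_per_quantile, dims = c(need, n_quantiles))
  prof <- as.matrix(V %*% member)
  colnames(prof) <- paste0("Q", seq_len(n_quantiles))
  gm <- as.vector(matrix(os$gauge_values[use], nrow = cells_per_quantile) |>
                    colMeans())
  structure(list(profile = prof, gauge_means = gm,
                 n_quantiles = n_quantiles,
                 cells_per_quantile = cells_per_quantile,
                 gauge_gene = os$gauge_gene, offset = offset),
            class = "quantile_profile")
}

#' Gene-gauge correlation over quantile bins
#'
#' Product-moment correlation of each gene's quantile-bin means against the
#' gauge's bin means. Genes with zero variance across bins are flagged
#' undefined rather than assigned a value.
#'
#' @param qp a [quantile_profile()].
#' @return data.frame `gene`, `cc`, `defined`.
#' @export
gauge_correlation <- function(qp) {
  stopifnot(inherits(qp, "quantile_profile"))
  g <- qp$gauge_means
  if (stats::var(g) == 0) stop("gauge has zero variance across bins")
  X <- qp$profile
  Xc <- X - rowMeans(X)
  gc <- g - mean(g)
  den <- sqrt(rowSums(Xc^2) * sum(gc^2))
  cc <- as.vector(Xc %*% gc) / den
  defined <- rowSums(Xc^2) > 0
  cc[!defined] <- NA_real_
  data.frame(gene = rownames(X), cc = cc, defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect high-correlation gene sets across samples
#'
#' Genes whose gene-gauge correlation exceeds `cc_min` in *every* sample
#' (strict in each).
#'
#' @param records named list (>= 2) of [gauge_correlation()] data.frames.
#' @param cc_min correlation threshold (default 0.90).
#' @return character vector of gene symbols.
#' @export
intersect_high_correlation <- function(records, cc_min = 0.90) {
  stopifnot(length(records) >= 2L)
  sets <- lapply(records, function(r)
    r$gene[!is.na(r$cc) & r$cc > cc_min])
  Reduce(intersect, sets)
}

#' Cytokeratin trajectory profiles
#'
#' Bin-mean trajectories (and gauge correlations) for the keratin genes in
#' the profile, selected by the KRT symbol prefix, or for an explicit gene
#' list.
#'
#' @param qp a [quantile_profile()].
#' @param genes gene symbols; default all `KRT`-prefixed genes present.
#' @return list with `trajectories` (genes x bins means) and `cc`
#'   (gauge correlations for those genes).
#' @export
keratin_profile <- function(qp, genes = NULL) {
  stopifnot(inherits(qp, "quantile_profile"))
  if (is.null(genes))
    genes <- rownames(qp$profile)[startsWith(rownames(qp$profile), "KRT")]
  genes <- intersect(genes, rownames(qp$profile))
  cc <- gauge_correlation(qp)
  list(trajectories = qp$profile[genes, , drop = FALSE],
       cc = cc[match(genes, cc$gene), , drop = FALSE])
}
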