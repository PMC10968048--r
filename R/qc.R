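#' Gene-family ratio statistics across domains
#'
#' Constancy control: within a single epithelial lineage, mitochondrial
#' (MT-) and ribosomal (RPS/RPL) gene expression should be flat along the
#' differentiation axis. For each family gene and each domain pair, the
#' ratio of domain mean expression is computed; the family mean +/- SD
#' summarises it, and a two-sided Welch test between consecutive pairs'
#' ratio sets probes for drift.
#'
#' @param nm a [norm_matrix()].
#' @param groups a [build_comparison_groups()] result.
#' @param prefixes gene-symbol prefixes defining the families.
#' @param pairs list of `c(groupA, groupB)` domain pairs (defaults to the
#'   D0/D123/D4i.1/D4i.2 ladder plus the overall D0 vs D4i.2 pair).
#' @param universe optional [select_gene_universe()]; families are
#'   restricted to it when given.
#' @return list with `stats` (family, pair, mean, sd, n, p_next: Welch p
#'   against the next pair's ratios) and `per_gene` (family, pair, gene,
#'   ratio).
#' @export
family_ratio_stats <- function(nm, groups,
                               prefixes = c("MT-", "RPS", "RPL"),
                               pairs = list(c("D0", "D123"),
                                            c("D123", "D4i.1"),
                                            c("D4i.1", "D4i.2"),
                                            c("D0", "D4i.2")),
                               universe = NULL) {
  stopifnot(inherits(nm, "norm_matrix"))
  pool <- if (is.null(universe)) nm$gene_ids else
    intersect(universe$genes, nm$gene_ids)
  pair_lab <- vapply(pairs, paste, character(1L), collapse = "v")
  stats_rows <- list()
  gene_rows <- list()
  for (pf in prefixes) {
    fam <- pool[startsWith(pool, pf)]
    if (length(fam) < 2L) {
      warning("family ", pf, " has fewer than 2 genes; skipped")
      next
    }
    ratios <- matrix(NA_real_, length(fam), length(pairs),
                     dimnames = list(fam, pair_lab))
    for (k in seq_along(pairs)) {
      ga <- groups$groups[[pairs[[k]][1L]]]
      gb <- groups$groups[[pairs[[k]][2L]]]
      mA <- as.vector(Matrix::rowMeans(nm$values[fam, ga, drop = FALSE]))
      mB <- as.vector(Matrix::rowMeans(nm$values[fam, gb, drop = FALSE]))
      r <- ifelse(mB > 0, mA / mB, NA_real_)
      ratios[, k] <- r
      gene_rows[[paste(pf, k)]] <- data.frame(
        family = pf, pair = pair_lab[k], gene = fam, ratio = r,
        stringsAsFactors = FALSE)
    }
    p_next <- rep(NA_real_, length(pairs))
    for (k in seq_len(length(pairs) - 1L)) {
      a <- ratios[, k]; b <- ratios[, k + 1L]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) >= 2L && length(b) >= 2L &&
          (stats::var(a) > 0 || stats::var(b) > 0))
        p_next[k] <- stats::t.test(a, b)$p.value
    }
    stats_rows[[pf]] <- data.frame(
      family = pf, pair = pair_lab,
      mean = colMeans(ratios, na.rm = TRUE),
      sd = apply(ratios, 2L, stats::sd, na.rm = TRUE),
      n = colSums(is.finite(ratios)),
      p_next = p_next, stringsAsFactors = FALSE)
  }
  list(stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
       per_gene = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))))
}

#' Calibrate the DEG ratio gate from invariant-family ratios
#'
#' The gate is set just above the most extreme between-domain ratio observed
#' among genes expected to be constant: `rho` is the maximum of every ratio
#' and its reciprocal, rounded up to 2 decimals. DEG calls then require a
#' ratio beyond `rho` (or below its reciprocal), screening out fluctuations
#' of the size seen in the constancy families.
#'
#' @param family_ratios numeric vector of per-gene between-domain ratios
#'   (e.g. the `per_gene$ratio` column of [family_ratio_stats()]).
#' @return list with `rho` and `reciprocal` (3 decimals).
#' @export
calibrate_ratio_gate <- function(family_ratios) {
  r <- family_ratios[is.finite(family_ratios) & family_ratios > 0]
  if (length(r) == 0L) stop("no finite positive ratios supplied")
  m <- max(pmax(r, 1 / r))
  rho <- ceiling(m * 100) / 100
  list(rho = rho, reciprocal = round(1 / rho, 3))
}

#' Genomic coverage fraction
#'
#' Percent of probed genes detected (at least one count in at least one
#' cell), rounded to integer percent.
#'
#' @param cm a [count_matrix()].
#' @return list with `percent`, `detected`, `probed`.
#' @export
coverage_fraction <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  detected <- sum(as.vector(Matrix::rowSums(cm$counts > 0)) > 0)
  list(percent = round(100 * detected / cm$probed_gene_count),
       detected = detected, probed = cm$probed_gene_count)
}

#' Sentinel-gene constancy report
#'
#' Tracks genes with a-priori expectations along the axis: genes expected to
#' correlate with differentiation (e.g. ALDH3A1, ALDH1A1, TKT, GJA1, KRT3)
#' and genes expected to be invariant (EEF1A1, EIF1, ACTG1, ACTB, GAPDH).
#' For each sentinel, per-domain mean expression and the BHp of each
#' adjacent-domain comparison are reported; transitions with `BHp >= alpha`
#' are marked `N.S.`.
#'
#' @param nm a [norm_matrix()].
#' @param groups a [build_comparison_groups()] result.
#' @param correlating,invariant sentinel symbol vectors.
#' @param transitions list of comparison pair labels (entries of
#'   `groups$pairs` or `"A-B"` group names).
#' @param universe optional gene universe for the per-comparison BH
#'   adjustment (defaults to all genes).
#' @param alpha significance threshold.
#' @return list with `report` (one row per sentinel x transition: means,
#'   BHp, R, signif) and `missing` (sentinels absent from the matrix).
#' @export
sentinel_report <- function(nm, groups,
                            correlating = c("ALDH3A1", "ALDH1A1", "TKT",
                                            "GJA1", "KRT3"),
                            invariant = c("EEF1A1", "EIF1", "ACTG1", "ACTB",
                                          "GAPDH"),
                            transitions = c("D0-D123", "D123-D4i.1",
                                            "D4i.1-D4i.2"),
                            universe = NULL, alpha = 0.01) {
  sentinels <- data.frame(
    gene = c(correlating, invariant),
    set = rep(c("correlating", "invariant"),
              c(length(correlating), length(invariant))),
    stringsAsFactors = FALSE)
  missing <- setdiff(sentinels$gene, nm$gene_ids)
  present <- sentinels[!(sentinels$gene %in% missing), , drop = FALSE]
  rows <- list()
  for (tr in transitions) {
    dt <- compare_domains(nm, groups, tr, universe = universe, alpha = alpha)
    rec <- dt$records[match(present$gene, dt$records$gene), , drop = FALSE]
    rows[[tr]] <- data.frame(
      gene = present$gene, set = present$set, transition = tr,
      mean_A = rec$mean_A, mean_B = rec$mean_B, R = rec$R, BHp = rec$BHp,
      signif = ifelse(!is.na(rec$BHp) & rec$BHp < alpha, "signif", "N.S."),
      stringsAsFactors = FALSE)
  }
  list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       missing = missing)
}
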