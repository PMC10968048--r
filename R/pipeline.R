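#' Run the full gauge-domain workflow
#'
#' Orchestrates the stages in analysis order — purge, MGC trim, unit-MGC
#' normalisation, accounting; amalgamation and gauge ordering; domain
#' segmentation and comparison groups; family/sentinel/coverage QC;
#' differential expression for the standard comparisons; trajectory cohorts;
#' quantile correlation — and writes every table as TSV into `out_dir`
#' together with a reproducible run manifest (no timestamps, so identical
#' configurations yield identical bundles).
#'
#' @param cms named list of [count_matrix()] objects (raw samples).
#' @param out_dir output directory.
#' @param panel a [marker_panel()].
#' @param mgc_low,mgc_high MGC trim bounds.
#' @param gauge_gene gauge symbol.
#' @param n_domains domains for segmentation.
#' @param manual_boundaries optional manual domain ends (switches
#'   segmentation to manual mode).
#' @param universe_size gene-universe size; capped at the detected gene
#'   count.
#' @param alpha,rho DEG thresholds.
#' @param interface_trim,post_d3_gap,window passed to
#'   [build_comparison_groups()].
#' @param comparisons comparison pair labels to run.
#' @param n_quantiles,cells_per_quantile quantile-profile settings
#'   (`cells_per_quantile = NULL` derives it from the cell count).
#' @param cc_min high-correlation threshold.
#' @return invisibly, a list with every intermediate object.
#' @export
run_pipeline <- function(cms, out_dir,
                         panel = marker_panel(),
                         mgc_low = 0.5, mgc_high = 2.5,
                         gauge_gene = "KRT12",
                         n_domains = 5L, manual_boundaries = NULL,
                         universe_size = 6647L,
                         alpha = 0.01, rho = 1.35,
                         interface_trim = 10L, post_d3_gap = 100L,
                         window = 1000L,
                         comparisons = c("D0-D1", "D1-D2", "D2-D3", "D1-D23",
                                         "D0-D123", "D123-D4i.1",
                                         "D4i.1-D4i.2"),
                         n_quantiles = 20L, cells_per_quantile = NULL,
                         cc_min = 0.90) {
  stopifnot(length(cms) >= 1L, !is.null(names(cms)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # 1. preprocess each sample
  prep <- lapply(names(cms), function(s) {
    cm <- cms[[s]]
    fl <- flag_cells(cm, panel)
    tr <- trim_by_mgc(cm, fl, low = mgc_low, high = mgc_high)
    nmx <- normalize_to_unit_mgc(tr$cm, sample_label = s)
    list(qc = tr$qc, cm = tr$cm, nm = nmx)
  })
  names(prep) <- names(cms)
  acct <- accounting(lapply(prep, function(p) list(qc = p$qc, cm = p$cm)),
                     gauge_gene = gauge_gene)
  wtsv(acct, "accounting.tsv")

  # 2. amalgamate and order along the gauge axis
  nm <- if (length(prep) > 1L)
    amalgamate(lapply(prep, `[[`, "nm")) else prep[[1L]]$nm
  os <- order_by_gauge(nm, gauge_gene)
  dp <- segment_domains(os, n_domains = n_domains,
                        mode = if (is.null(manual_boundaries)) "auto"
                               else "manual",
                        manual_boundaries = manual_boundaries)
  wtsv(dp$table, "domains.tsv")
  groups <- build_comparison_groups(dp, interface_trim = interface_trim,
                                    post_d3_gap = post_d3_gap,
                                    window = window)
  wtsv(groups$trim_log, "trim_log.tsv")

  # 3. QC: universe, coverage, families, sentinels
  universe <- select_gene_universe(os$matrix,
                                   min(universe_size,
                                       length(os$matrix$gene_ids)))
  cov <- coverage_fraction(cms[[1L]])
  fam <- family_ratio_stats(os$matrix, groups, universe = universe)
  if (!is.null(fam$stats)) wtsv(fam$stats, "family_ratios.tsv")
  if (!is.null(fam$per_gene)) wtsv(fam$per_gene, "family_ratios_per_gene.tsv")
  sent <- sentinel_report(os$matrix, groups, universe = universe,
                          alpha = alpha)
  wtsv(sent$report, "sentinels.tsv")

  # 4. differential expression
  degs <- lapply(comparisons, function(pr)
    compare_domains(os$matrix, groups, pr, universe = universe,
                    alpha = alpha, rho = rho))
  names(degs) <- comparisons
  for (pr in comparisons)
    wtsv(degs[[pr]]$records,
         paste0("deg_", gsub("[^A-Za-z0-9.]+", "_", pr), ".tsv"))
  summ <- deg_summary(degs)
  wtsv(summ, "deg_summary.tsv")

  # 5. trajectory cohorts over the informative transitions
  informative <- intersect(c("D0-D1", "D123-D4i.1", "D4i.1-D4i.2"),
                           comparisons)
  cohorts <- NULL
  if (length(informative) >= 2L) {
    cohorts <- classify_trajectory(degs[informative], alpha = alpha,
                                   rho = rho)
    wtsv(cohorts, "cohorts.tsv")
  }

  # 6. quantile correlation along the axis
  qp <- quantile_profile(os, n_quantiles = n_quantiles,
                         cells_per_quantile = cells_per_quantile,
                         genes = universe$genes)
  corr <- gauge_correlation(qp)
  wtsv(corr, "correlation.tsv")

  manifest <- c(paste0("package: krtgauge ",
                       as.character(utils::packageVersion("krtgauge"))),
                paste0("samples: ", paste(names(cms), collapse = ", ")),
                paste0("cells: ", paste(vapply(cms, function(x)
                  ncol(x$counts), integer(1L)), collapse = ", ")),
                paste0("gauge_gene: ", gauge_gene),
                paste0("mgc_bounds: (", mgc_low, ", ", mgc_high, ")"),
                paste0("universe_size: ", universe$size),
                paste0("alpha: ", alpha, "; rho: ", rho),
                paste0("n_domains: ", n_domains),
                paste0("coverage_percent: ", cov$percent))
  manifest <- c(manifest, paste0("config_md5: ",
                                 .manifest_md5(manifest)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(prep = prep, accounting = acct, nm = nm, os = os, dp = dp,
                 groups = groups, universe = universe, coverage = cov,
                 family = fam, sentinels = sent, degs = degs,
                 deg_summary = summ, cohorts = cohorts, qp = qp,
                 correlation = corr, out_dir = out_dir))
}

# md5 of the serialised configuration lines (via a temp file; tools::md5sum
# is file-based).
.manifest_md5 <- function(lines) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf)
  unname(tools::md5sum(tf))
}
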