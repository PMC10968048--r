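# Shared fixtures: a marker panel with the config-supplied blood/Langerhans
# sets, and small simulation configurations sized for unit tests.

test_panel <- function() {
  marker_panel(blood = c("PTPRC", "CD52"), langerhans = "CD207")
}

small_cfg <- function(seed, n_cells = 1500, n_genes = 800, ...) {
  sim_config(n_cells = n_cells, n_genes = n_genes, seed = seed, ...)
}

# A compact three-replicate study plus its preprocessed, ordered amalgam.
# Window geometry is scaled down with the cell counts; the module step
# fraction matches the scaled windows.
small_study <- function(seed, n_genes = 1200,
                        n_cells = c(1800, 700, 600),
                        gap = 50L, window = 350L) {
  study <- sim_study(seed = seed, n_genes = n_genes, n_cells = n_cells,
                     d4_step_frac = (gap + window) / (0.40 * 0.72 *
                                                        0.93 * sum(n_cells)))
  study
}

# Preprocess (purge + trim + normalise) every sample of a study and return
# the ordered amalgam plus groups.
prep_study <- function(study, gap = 50L, window = 350L,
                       universe_size = NULL) {
  prep <- lapply(names(study), function(s) {
    cm <- study[[s]]$cm
    fl <- flag_cells(cm, test_panel())
    tr <- trim_by_mgc(cm, fl)
    list(qc = tr$qc, cm = tr$cm,
         nm = normalize_to_unit_mgc(tr$cm, sample_label = s))
  })
  names(prep) <- names(study)
  nm <- amalgamate(lapply(prep, `[[`, "nm"))
  os <- order_by_gauge(nm, "KRT12")
  dp <- segment_domains(os)
  groups <- build_comparison_groups(dp, post_d3_gap = gap, window = window)
  uni <- select_gene_universe(os$matrix,
                              if (is.null(universe_size))
                                length(os$matrix$gene_ids) else universe_size)
  list(prep = prep, nm = nm, os = os, dp = dp, groups = groups,
       universe = uni)
}

# Combined truth tables of a study, keyed by cell id (amalgam ids carry an
# "s<i>:" prefix when barcodes collide; strip it).
study_truth_cells <- function(study) {
  do.call(rbind, lapply(study, function(s) s$truth$cells))
}

match_truth <- function(os, truth_cells) {
  ids <- sub("^s[0-9]+:", "", os$matrix$cell_ids)
  truth_cells[match(ids, truth_cells$cell_id), , drop = FALSE]
}

# Independent step-up implementation used as the BH oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  res <- numeric(n)
  res[o] <- pmin(adj, 1)
  res
}
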