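#' Simulation configuration
#'
#' Defines a synthetic limbal-corneal sample: negative-binomial UMI counts
#' for a gene panel with a planted differentiation axis. Defaults emulate the
#' LiPe-1 study conditions: ~5,800 cells of which ~6% carry melanocyte
#' markers (one fifth of those as epithelial-melanocyte duplets), a handful
#' of conjunctival/blood/Langerhans cells, ~24% decaying cells with expected
#' MGC below 0.5 and ~4% duplet-like cells above 2.5, and kept epithelial
#' cells split over five gauge domains (32% gauge-negative, 60% of kept
#' cells in D0-D3). Gauge expression is 0 in D0, rises linearly within each
#' of D1-D3 (ceilings anchored at 1.77, 3.18 and 5.32 A.U., the printed
#' D0-D3 ceiling, with max(D23) = 3 x max(D1)), and ramps linearly in rank
#' across D4 into the hundreds of A.U.
#'
#' Planted differential-expression modules change at the three informative
#' transitions (D0 to D1, D123 to the first D4 window, first to second D4
#' window) by `module_lfc` log2 units per transition. MT-/RPS/RPL family
#' genes and invariant sentinels are constant across the axis; correlating
#' sentinels and a GPHA2-like early-D4 peak module provide known trajectory
#' shapes.
#'
#' @param n_cells total cells in the sample (before any purging).
#' @param n_genes number of gene rows emitted.
#' @param probed_gene_count assay denominator for MGC; defaults to
#'   `round(n_genes / 0.6)` (about 60% of probed genes detected, as in deep
#'   10x runs), floored at 12000 so marker counts stay on a realistic scale.
#' @param sample_label sample name.
#' @param domain_props named proportions of kept epithelial cells per domain.
#' @param gauge_gene gauge symbol (default KRT12).
#' @param gauge_ranges list of `c(lo, hi)` A.U. targets for D1-D4.
#' @param gauge_noise_sd lognormal sd of the multiplicative jitter applied to
#'   the gauge target before count rounding.
#' @param frac_melanocyte,frac_langerhans,frac_blood,frac_conjunctival
#'   contaminant fractions of total cells.
#' @param duplet_share_of_melanocyte fraction of melanocyte-marker columns
#'   that are epithelial-melanocyte duplets.
#' @param frac_dying,frac_highcount fractions of epithelial cells with scaled
#'   down (expected MGC < 0.5) or scaled-up (> 2.5) library size.
#' @param modules named integer vector of planted module sizes
#'   (`continuous_down`, `continuous_up`, `d0d1_only_down`, `d0d1_only_up`).
#' @param module_lfc absolute log2 fold change per transition.
#' @param n_family named integer vector: genes per constancy family
#'   (`mt`, `rps`, `rpl`).
#' @param d4_step_frac fraction of the D4 gauge range at which the
#'   third-transition module step occurs. Positions along D4 are defined on
#'   the gauge-value scale (shared across replicate samples, so the step
#'   survives amalgamation); the default 0.41 places it at the boundary
#'   between the two 1000-cell analysis windows of a study-sized amalgam
#'   (1100 of ~2680 D4 cells).
#' @param nb_size negative-binomial size (dispersion = 1/size).
#' @param baseline_sdlog sd(log) of the log-normal gene baseline draw.
#' @param deterministic if TRUE, counts are `round(mu)` instead of NB draws
#'   (noiseless mode for identity checks).
#' @param seed RNG seed; mandatory at simulation time.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 5843,
                       n_genes = 8000,
                       probed_gene_count = NULL,
                       sample_label = "LiPe-1",
                       domain_props = c(D0 = 0.32, D1 = 0.17, D2 = 0.07,
                                        D3 = 0.04, D4 = 0.40),
                       gauge_gene = "KRT12",
                       gauge_ranges = list(D1 = c(0.4, 1.77),
                                           D2 = c(1.77, 3.18),
                                           D3 = c(3.18, 5.32),
                                           D4 = c(5.32, 200)),
                       gauge_noise_sd = 0.05,
                       frac_melanocyte = 0.06,
                       frac_langerhans = 0.0005,
                       frac_blood = 0.0005,
                       frac_conjunctival = 0.0015,
                       duplet_share_of_melanocyte = 0.2,
                       frac_dying = 0.24,
                       frac_highcount = 0.04,
                       modules = c(continuous_down = 40, continuous_up = 40,
                                   d0d1_only_down = 30, d0d1_only_up = 20),
                       module_lfc = 1,
                       d4_step_frac = 0.41,
                       n_family = c(mt = 12, rps = 34, rpl = 44),
                       nb_size = 2,
                       baseline_sdlog = 1.6,
                       deterministic = FALSE,
                       seed = NULL) {
  if (is.null(probed_gene_count))
    probed_gene_count <- max(round(n_genes / 0.6), 12000L)
  props <- domain_props / sum(domain_props)
  stopifnot(all(props >= 0), length(props) == 5L,
            identical(names(props), c("D0", "D1", "D2", "D3", "D4")))
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              probed_gene_count = as.integer(probed_gene_count),
              sample_label = sample_label, domain_props = props,
              gauge_gene = gauge_gene, gauge_ranges = gauge_ranges,
              gauge_noise_sd = gauge_noise_sd,
              frac_melanocyte = frac_melanocyte,
              frac_langerhans = frac_langerhans, frac_blood = frac_blood,
              frac_conjunctival = frac_conjunctival,
              duplet_share_of_melanocyte = duplet_share_of_melanocyte,
              frac_dying = frac_dying, frac_highcount = frac_highcount,
              modules = modules, module_lfc = module_lfc,
              d4_step_frac = d4_step_frac,
              n_family = n_family, nb_size = nb_size,
              baseline_sdlog = baseline_sdlog,
              deterministic = deterministic, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# Reserved genes: symbol, baseline mean count at unit library scale, module.
.reserved_genes <- function() {
  data.frame(
    gene_id = c("KRT12", "KRT5", "KRT14", "KRT15", "KRT3", "KRT6A", "KRT13",
                "KRT24", "KRT75", "GPHA2",
                "DCT", "TYR", "TYRP1", "MLANA", "AQP5", "PTPRC", "CD52",
                "CD207",
                "ALDH3A1", "ALDH1A1", "TKT", "GJA1",
                "EEF1A1", "EIF1", "ACTG1", "ACTB", "GAPDH"),
    baseline = c(0, 40, 30, 18, 1, 10, 3, 4, 2, 3,
                 0, 0, 0, 0, 0, 0, 0, 0,
                 4, 3, 3, 2,
                 80, 60, 70, 90, 60),
    module = c("gauge", "none", "krt_down", "krt_down", "corr_up", "none",
               "none", "none", "gpha2_like", "gpha2_like",
               "marker_melanocyte", "marker_melanocyte", "marker_melanocyte",
               "marker_melanocyte", "marker_conjunctival", "marker_blood",
               "marker_blood", "marker_langerhans",
               "corr_up", "corr_up", "corr_up", "corr_up",
               "sentinel_invariant", "sentinel_invariant",
               "sentinel_invariant", "sentinel_invariant",
               "sentinel_invariant"),
    stringsAsFactors = FALSE)
}

# Per-module expression multipliers at the six axis levels
# (D0, D1, D2, D3, D4 first window incl. gap, D4 beyond first window).
.module_levels <- function(module, lfc) {
  u <- 2^lfc
  r <- 2^(-lfc)
  switch(module,
         continuous_down = c(1, r, r, r, r^2, r^3),
         continuous_up   = c(1, u, u, u, u^2, u^3),
         d0d1_only_down  = c(1, r, r, r, r, r),
         d0d1_only_up    = c(1, u, u, u, u, u),
         corr_up         = c(1, 1.5, 1.5, 1.5, 2, 3),
         krt_down        = c(1, 0.8, 0.8, 0.8, 0.6, 0.4),
         gpha2_like      = c(1, 1, 1, 1, 1, 1),
         c(1, 1, 1, 1, 1, 1))
}

# Continuous within-D4 multiplier for ramp-shaped modules, as a function of
# the fraction f of the D4 gauge range the cell has reached (value-scale, so
# consistent across replicate samples).
.d4_ramp <- function(module, f) {
  f <- pmin(pmax(f, 0), 1)
  switch(module,
         corr_up    = 1.5 * (3.5 / 1.5)^f,  # 1.5x at D4 start to 3.5x at end
         krt_down   = 0.7 * (3 / 7)^f,      # 0.7x down to 0.3x
         gpha2_like = 0.2 + 6 * exp(-f / 0.11),  # early-D4 peak, fast decay
         rep(1, length(f)))
}

# Target total baseline mass (counts per unit library scale) per planted
# module. The up/down masses are chosen so the transcript mass gained by
# upregulated modules at each axis level is offset by the mass lost by the
# downregulated ones: unit-MGC normalisation is zero-sum, so an unbalanced
# design would leak planted fold changes into every constant gene.
.module_mass <- c(continuous_up = 10, continuous_down = 160,
                  d0d1_only_down = 120, d0d1_only_up = 136)

.build_genes <- function(cfg) {
  res <- .reserved_genes()
  fam <- data.frame(
    gene_id = c(paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5",
                                "ND6", "CO1", "CO2", "CO3", "ATP6", "ATP8",
                                sprintf("X%02d", seq_len(max(0, cfg$n_family[["mt"]] - 12L))))[
                                  seq_len(cfg$n_family[["mt"]])]),
                paste0("RPS", seq_len(cfg$n_family[["rps"]])),
                paste0("RPL", seq_len(cfg$n_family[["rpl"]]))),
    baseline = NA_real_,
    module = rep("family", sum(cfg$n_family)),
    stringsAsFactors = FALSE)
  fam$baseline <- c(stats::rlnorm(cfg$n_family[["mt"]], log(30), 0.3),
                    stats::rlnorm(cfg$n_family[["rps"]], log(60), 0.3),
                    stats::rlnorm(cfg$n_family[["rpl"]], log(45), 0.3))
  mods <- rep(names(cfg$modules), cfg$modules)
  mod <- data.frame(
    gene_id = sprintf("SIM.%s.%03d", toupper(mods),
                      unlist(lapply(cfg$modules, seq_len))),
    baseline = stats::rlnorm(length(mods), 0, 0.25),
    module = mods, stringsAsFactors = FALSE)
  for (mn in unique(mods)) {
    sel <- mod$module == mn
    target <- if (mn %in% names(.module_mass)) .module_mass[[mn]] else
      4 * sum(sel)
    mod$baseline[sel] <- mod$baseline[sel] * (target / sum(mod$baseline[sel]))
  }
  n_special <- nrow(res) + nrow(fam) + nrow(mod)
  if (n_special > cfg$n_genes)
    stop("infeasible config: ", n_special, " reserved/module/family genes ",
         "exceed n_genes = ", cfg$n_genes)
  n_free <- cfg$n_genes - n_special
  free <- data.frame(gene_id = sprintf("GENE%05d", seq_len(n_free)),
                     baseline = stats::rlnorm(n_free, 0, cfg$baseline_sdlog),
                     module = "none", stringsAsFactors = FALSE)
  genes <- rbind(res, fam, mod, free)
  # scale the free pool so a unit-scale cell has total counts = probed
  # genes; cap any single free gene at 0.5% of the cell's transcript mass
  # (no gene dominates a UMI library) so realized library sizes concentrate
  # tightly around their expectation
  reserved_mass <- sum(genes$baseline[genes$module != "none" |
                                        genes$gene_id %in% res$gene_id])
  target_free <- cfg$probed_gene_count - reserved_mass
  if (target_free <= 0)
    stop("infeasible config: reserved gene mass exceeds probed_gene_count")
  if (n_free > 0) {
    b <- free$baseline
    cap <- 0.005 * cfg$probed_gene_count
    for (it in 1:3) b <- pmin(b * (target_free / sum(b)), cap)
    genes$baseline[genes$module == "none" &
                     !(genes$gene_id %in% res$gene_id)] <- b
  }
  # interleave so module/family genes are not clustered at fixed rows
  genes <- genes[sample.int(nrow(genes)), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Simulate a synthetic limbal-corneal sample
#'
#' Draws a genes-x-cells UMI [count_matrix()] plus the full ground truth
#' needed to score every pipeline stage: per-cell type, domain and axis
#' position; per-gene baseline, module label and per-transition log2 fold
#' changes. Contaminant cells carry their lineage markers and lack the
#' epithelial keratins; decaying cells and duplets are library-size scaled
#' so their expected MGC lands below 0.5 or above 2.5. The gauge gene is
#' exactly zero in D0 and its count is `round(target A.U. x library scale)`
#' elsewhere (floored at 1 outside D0), so the sorted normalised gauge curve
#' reproduces the planted axis up to UMI quantisation.
#'
#' @param cfg a [sim_config()]; `cfg$seed` must be set.
#' @param genes optional pre-built gene panel (data.frame from an earlier
#'   simulation's `truth$genes`), so replicate samples share one biology.
#' @return list with `cm` (a [count_matrix()]) and `truth` (list with
#'   `cells` and `genes` data.frames, `domain_sizes`, `config`).
#' @export
simulate_sample <- function(cfg, genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$seed)) stop("cfg$seed is mandatory for reproducibility")
  set.seed(cfg$seed)
  n <- cfg$n_cells

  # --- cell layout ---------------------------------------------------------
  n_mel <- round(cfg$frac_melanocyte * n)
  n_dup <- round(cfg$duplet_share_of_melanocyte * n_mel)
  n_mel_pure <- n_mel - n_dup
  n_lang <- round(cfg$frac_langerhans * n)
  n_blood <- round(cfg$frac_blood * n)
  n_conj <- round(cfg$frac_conjunctival * n)
  n_epi <- n - n_mel - n_lang - n_blood - n_conj
  if (n_epi <= 10) stop("infeasible config: almost no epithelial cells")
  n_dying <- round(cfg$frac_dying * n_epi)
  n_high <- round(cfg$frac_highcount * n_epi)
  n_kept <- n_epi - n_dying - n_high

  d_sizes <- floor(cfg$domain_props * n_kept)
  d_sizes["D4"] <- n_kept - sum(d_sizes[c("D0", "D1", "D2", "D3")])

  type <- c(rep("epithelial", n_kept), rep("dying", n_dying),
            rep("highcount", n_high), rep("melanocyte", n_mel_pure),
            rep("duplet", n_dup), rep("langerhans", n_lang),
            rep("blood", n_blood), rep("conjunctival", n_conj))
  n_tot <- length(type)
  domain <- rep(NA_character_, n_tot)
  domain[seq_len(n_kept)] <- rep(names(d_sizes), d_sizes)
  # non-kept epithelial-profile cells get a domain for their expression
  # program, but no axis rank
  other_epi <- which(type %in% c("dying", "highcount", "duplet",
                                 "conjunctival"))
  if (length(other_epi))
    domain[other_epi] <- sample(names(d_sizes), length(other_epi),
                                replace = TRUE, prob = cfg$domain_props)

  axis_rank <- rep(NA_integer_, n_tot)
  axis_rank[seq_len(n_kept)] <- seq_len(n_kept)
  d4_rank <- rep(NA_integer_, n_tot)
  kept_d4 <- which(!is.na(axis_rank) & domain == "D4")
  d4_rank[kept_d4] <- seq_along(kept_d4)
  n4 <- length(kept_d4)
  d4_rank[setdiff(which(domain == "D4"), kept_d4)] <- max(1L, n4 %/% 2L)

  # library scale: kept cells well inside the (0.5, 2.5) MGC gate, dying
  # cells well below it, duplet-like cells well above — the margins exceed
  # the realized-total sampling noise so the trim recovers the partition
  s <- numeric(n_tot)
  kept_like <- type %in% c("epithelial", "melanocyte", "langerhans", "blood",
                           "conjunctival")
  s[kept_like] <- pmin(pmax(stats::rlnorm(sum(kept_like), 0, 0.18), 0.70), 1.90)
  s[type == "dying"] <- stats::runif(n_dying, 0.15, 0.35)
  s[type == "highcount"] <- stats::runif(n_high, 3.2, 4.0)
  s[type == "duplet"] <- stats::runif(n_dup, 3.2, 4.0)

  # gauge target in A.U. along the axis (0 in D0, linear within D1-D4)
  gauge_target <- numeric(n_tot)
  for (d in c("D1", "D2", "D3", "D4")) {
    rng <- cfg$gauge_ranges[[d]]
    idx <- which(domain == d & !is.na(axis_rank))
    nd <- length(idx)
    if (nd > 0)
      gauge_target[idx] <- rng[1] + (rng[2] - rng[1]) *
        (seq_len(nd) - 1) / max(nd - 1, 1)
    oth <- setdiff(which(domain == d), idx)
    if (length(oth)) gauge_target[oth] <- mean(rng)
  }

  # --- gene panel ----------------------------------------------------------
  if (is.null(genes)) genes <- .build_genes(cfg)
  g_id <- genes$gene_id
  lvl <- vapply(genes$module, .module_levels, numeric(6L), lfc = cfg$module_lfc)
  lvl <- t(lvl)  # n_genes x 6
  colnames(lvl) <- c("D0", "D1", "D2", "D3", "D4a", "D4b")
  ramp_rows <- which(genes$module %in% c("corr_up", "krt_down", "gpha2_like"))
  gauge_row <- match(cfg$gauge_gene, g_id)
  mel_rows <- which(genes$module == "marker_melanocyte")
  blood_rows <- which(genes$module == "marker_blood")
  lang_rows <- which(genes$module == "marker_langerhans")
  conj_rows <- which(genes$module == "marker_conjunctival")
  epi_req_rows <- match(c("KRT5", "KRT14", "KRT12"), g_id)

  # fraction of the D4 gauge range reached (value scale); level index per
  # cell with D4 split at the configured third-transition step
  d4rng <- cfg$gauge_ranges[["D4"]]
  d4_frac <- rep(NA_real_, n_tot)
  in_d4 <- which(domain == "D4" & !is.na(domain))
  d4_frac[in_d4] <- (gauge_target[in_d4] - d4rng[1]) / (d4rng[2] - d4rng[1])
  lev <- ifelse(is.na(domain), "D0", domain)
  lev[in_d4] <- ifelse(d4_frac[in_d4] <= cfg$d4_step_frac, "D4a", "D4b")
  lev_idx <- match(lev, colnames(lvl))

  # --- emission ------------------------------------------------------------
  chunks <- split(seq_len(n_tot), ceiling(seq_len(n_tot) / 200L))
  tri_i <- vector("list", length(chunks))
  tri_j <- vector("list", length(chunks))
  tri_x <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    cells <- chunks[[ci]]
    M <- lvl[, lev_idx[cells], drop = FALSE]  # n_genes x b multipliers
    d4c <- which(domain[cells] == "D4" & !is.na(domain[cells]))
    if (length(d4c) && length(ramp_rows)) {
      fr <- d4_frac[cells[d4c]]
      for (g in ramp_rows)
        M[g, d4c] <- .d4_ramp(genes$module[g], fr)
    }
    mu <- (genes$baseline * M) %*% diag(s[cells], nrow = length(cells))
    # contaminant overrides
    for (k in seq_along(cells)) {
      cc <- cells[k]
      if (type[cc] %in% c("melanocyte", "langerhans", "blood")) {
        mu[stats::na.omit(epi_req_rows), k] <- 0
        rows <- switch(type[cc], melanocyte = mel_rows,
                       langerhans = lang_rows, blood = blood_rows)
        if (length(rows)) mu[rows, k] <- 30 * s[cc]
      } else if (type[cc] == "duplet") {
        if (length(mel_rows)) mu[mel_rows, k] <- 30 * s[cc]
      } else if (type[cc] == "conjunctival") {
        if (length(conj_rows)) mu[conj_rows, k] <- 25 * s[cc]
      }
    }
    mu[gauge_row, ] <- 0
    # gauge counts: integer realisation of the target A.U. at the cell's scale
    gt <- gauge_target[cells]
    jit <- if (cfg$deterministic || cfg$gauge_noise_sd == 0) 1 else
      exp(stats::rnorm(length(cells), 0, cfg$gauge_noise_sd))
    gct <- round(gt * s[cells] * jit)
    pos <- gt > 0 & type[cells] %in% c("epithelial", "dying", "highcount",
                                       "duplet")
    gct[pos] <- pmax(1, gct[pos])
    gct[!pos & gt > 0] <- 0
    # calibrate each column's non-gauge expected mass so the cell's expected
    # total equals lib_scale x probed genes (MGC margins are then exact)
    mass <- colSums(mu)
    f <- (s[cells] * cfg$probed_gene_count - gct) / mass
    mu <- mu * rep(f, each = nrow(mu))
    cnt <- if (cfg$deterministic) round(mu) else
      matrix(stats::rnbinom(length(mu), size = cfg$nb_size, mu = as.vector(mu)),
             nrow = nrow(mu))
    cnt[gauge_row, ] <- gct
    # guarantee lineage identity for epithelial-profile cells
    epi_prof <- type[cells] %in% c("epithelial", "dying", "highcount",
                                   "conjunctival", "duplet")
    none_expr <- colSums(cnt[stats::na.omit(epi_req_rows), , drop = FALSE] >= 1) == 0
    fix <- which(epi_prof & none_expr)
    if (length(fix)) cnt[epi_req_rows[1L], fix] <- 1
    nz <- which(cnt > 0)
    tri_i[[ci]] <- ((nz - 1L) %% nrow(cnt)) + 1L
    tri_j[[ci]] <- cells[((nz - 1L) %/% nrow(cnt)) + 1L]
    tri_x[[ci]] <- cnt[nz]
  }
  counts <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                                 x = unlist(tri_x),
                                 dims = c(cfg$n_genes, n_tot))

  cell_ids <- sprintf("%s_BC%05d", cfg$sample_label, seq_len(n_tot))
  perm <- sample.int(n_tot)
  counts <- counts[, perm, drop = FALSE]

  cells_truth <- data.frame(
    cell_id = cell_ids,
    type = type[perm],
    status = ifelse(type[perm] == "epithelial", "kept",
                    ifelse(type[perm] %in% c("dying", "highcount"),
                           type[perm], "contaminant")),
    domain = domain[perm],
    axis_rank = axis_rank[perm],
    d4_rank = d4_rank[perm],
    gauge_target = gauge_target[perm],
    lib_scale = s[perm],
    stringsAsFactors = FALSE)

  genes_truth <- genes
  genes_truth$lfc_t1 <- log2(lvl[, "D1"] / lvl[, "D0"])
  genes_truth$lfc_t2 <- log2(lvl[, "D4a"] / lvl[, "D1"])
  genes_truth$lfc_t3 <- log2(lvl[, "D4b"] / lvl[, "D4a"])
  ramp <- genes$module %in% c("corr_up", "krt_down", "gpha2_like")
  genes_truth$lfc_t2[ramp] <- NA_real_
  genes_truth$lfc_t3[ramp] <- NA_real_

  cm <- count_matrix(counts, gene_ids = g_id, cell_ids = cell_ids,
                     probed_gene_count = cfg$probed_gene_count)
  list(cm = cm,
       truth = list(cells = cells_truth, genes = genes_truth,
                    domain_sizes = d_sizes, n_kept = n_kept,
                    gauge_gene = cfg$gauge_gene, config = cfg))
}

#' Simulate a replicate study
#'
#' Three LiPe-like replicate samples with the study's per-sample cell totals
#' and melanocyte loads, sharing one gene panel design (same seed offsets, so
#' gene identities align across samples for amalgamation).
#'
#' @param seed integer base seed.
#' @param n_genes genes per sample.
#' @param n_cells per-sample totals (default the study's 5843/2234/1981).
#' @param frac_melanocyte per-sample melanocyte fractions.
#' @param ... further arguments passed to [sim_config()].
#' @return named list of `simulate_sample()` results.
#' @export
sim_study <- function(seed, n_genes = 8000,
                      n_cells = c(5843L, 2234L, 1981L),
                      frac_melanocyte = c(0.10, 0.064, 0.02), ...) {
  labs <- paste0("LiPe-", seq_along(n_cells))
  base_cfg <- sim_config(n_cells = n_cells[1L], n_genes = n_genes,
                         sample_label = labs[1L],
                         frac_melanocyte = frac_melanocyte[1L],
                         seed = seed, ...)
  set.seed(seed)
  panel <- .build_genes(base_cfg)
  out <- lapply(seq_along(n_cells), function(i) {
    cfg <- sim_config(n_cells = n_cells[i], n_genes = n_genes,
                      sample_label = labs[i],
                      frac_melanocyte = frac_melanocyte[i],
                      seed = seed + (i - 1L) * 1000L, ...)
    simulate_sample(cfg, genes = panel)
  })
  names(out) <- labs
  out
}

#' Write a simulated sample to disk
#'
#' Writes the counts in a standard dialect (`csv`: genes-x-cells with a
#' barcode header; `mtx`: MatrixMarket plus `features.tsv`/`barcodes.tsv`)
#' and the ground-truth tables as TSV. Output bytes are deterministic for a
#' given simulation.
#'
#' @param sim result of [simulate_sample()].
#' @param dir output directory (created if needed).
#' @param dialect `"csv"` or `"mtx"`.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(sim, dir, dialect = c("csv", "mtx")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- sim$cm
  paths <- character(0)
  if (dialect == "csv") {
    p <- file.path(dir, "counts.csv")
    dense <- as.matrix(cm$counts)
    lines <- c(paste(c("gene", cm$cell_ids), collapse = ","),
               paste(cm$gene_ids,
                     apply(dense, 1L, paste, collapse = ","), sep = ","))
    writeLines(lines, p)
    paths <- p
  } else {
    pm <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(as(cm$counts, "CsparseMatrix"), pm)
    pf <- file.path(dir, "features.tsv")
    writeLines(paste(cm$gene_ids, cm$gene_ids, "Gene Expression", sep = "\t"),
               pf)
    pb <- file.path(dir, "barcodes.tsv")
    writeLines(cm$cell_ids, pb)
    paths <- c(pm, pf, pb)
  }
  tc <- file.path(dir, "truth_cells.tsv")
  utils::write.table(sim$truth$cells, tc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tg <- file.path(dir, "truth_genes.tsv")
  utils::write.table(sim$truth$genes, tg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tc, tg))
}

#' Piecewise-linear gauge curve generator
#'
#' Generates a sorted-gauge-style curve: continuous piecewise-linear values
#' over ranks `1..n` with segment boundaries and slopes supplied, plus
#' optional Gaussian noise. Used to exercise the domain segmentation fit
#' against a known changepoint structure.
#'
#' @param n number of ranks.
#' @param breaks ranks at which a new segment starts (first segment starts
#'   at 1); e.g. `c(101, 201, 301, 401)` for segments of 100.
#' @param slopes one slope per segment (`length(breaks) + 1`).
#' @param noise_sd Gaussian noise sd added to the values.
#' @return numeric vector of length `n`.
#' @export
simulate_gauge_curve <- function(n, breaks, slopes, noise_sd = 0) {
  stopifnot(length(slopes) == length(breaks) + 1L,
            all(breaks > 1), all(breaks <= n), !is.unsorted(breaks))
  seg <- findInterval(seq_len(n), c(1, breaks))
  incr <- slopes[seg]
  v <- cumsum(c(0, incr[-1L]))
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  v
}
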