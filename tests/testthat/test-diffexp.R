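test_that("gene universe ranks by total expression with symbol tie-break", {
  vals <- rbind(A = c(5, 5), B = c(4, 3), D = c(3, 4), C = c(1, 1),
                E = c(0, 0))
  nm <- norm_matrix(vals, rownames(vals), c("c1", "c2"), 100)
  u <- select_gene_universe(nm, 3)
  expect_equal(u$genes, c("A", "B", "D"))  # B and D tie at 7: alphabetical
  expect_equal(select_gene_universe(nm, 5)$genes, c("A", "B", "D", "C", "E"))
  expect_error(select_gene_universe(nm, 0), "positive")
  expect_error(select_gene_universe(nm, 6), "exceeds")
  # ranking equals an independent sort of row sums
  sim <- simulate_sample(small_cfg(19, n_cells = 300, n_genes = 600))
  nm2 <- normalize_to_unit_mgc(sim$cm)
  u2 <- select_gene_universe(nm2, 600)
  tot <- rowSums(as.matrix(nm2$values))
  expect_equal(unname(u2$totals), unname(tot[order(-tot, names(tot))]))
})

test_that("the per-gene test matches the closed-form Welch computation", {
  # hand example: a = (1,2,3), b = (2,4,9); means 2 and 5, variances 1 and
  # 13, t = -3/sqrt(14/3) = -1.38873, df = 2.30588 -> p = 0.2838344
  expect_equal(gene_test(c(1, 2, 3), c(2, 4, 9)), 0.2838344, tolerance = 1e-6)
  # identical groups carry no evidence
  expect_equal(gene_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(gene_test(rep(2, 5), rep(2, 4)), 1)
  expect_equal(gene_test(rep(2, 5), rep(3, 4)), 0)
  expect_error(gene_test(1, c(1, 2)), "at least 2")
  set.seed(1)
  a <- rnorm(100, 2); b <- rnorm(100, 0)
  expect_lt(gene_test(a, b), 1e-10)
  expect_lt(gene_test(a, b, method = "mann_whitney"), 1e-10)
})

test_that("vectorised Welch agrees with stats::t.test row by row", {
  set.seed(7)
  A <- matrix(rnbinom(50 * 30, mu = 3, size = 2), 50)
  B <- matrix(rnbinom(50 * 40, mu = 4, size = 2), 50)
  w <- krtgauge:::.welch_rows(A, B)
  for (i in c(1, 10, 25, 50)) {
    if (var(A[i, ]) == 0 && var(B[i, ]) == 0) next
    expect_equal(w$p[i], t.test(A[i, ], B[i, ])$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "in \\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(200)^(1 + i %% 3)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(!is.unsorted(adj[o]))
  }
})

test_that("expression ratios reproduce printed arithmetic and symmetry", {
  # the gauge's printed window means: 37.1 and 127.3 A.U. give 1/R = 3.43
  r <- expression_ratio(37.1, 127.3)
  expect_equal(round(r$inv_R, 2), 3.43)
  expect_equal(expression_ratio(c(2, 4), c(2, 4))$R, 1)
  set.seed(3)
  a <- runif(20); b <- runif(20)
  expect_equal(expression_ratio(a, b)$R * expression_ratio(b, a)$R, 1)
  expect_equal(expression_ratio(c(1, 1), c(0, 0))$status, "infinite")
  expect_equal(expression_ratio(c(0, 0), c(0, 0))$status, "undefined")
})

test_that("DEG calls apply the BHp threshold and the ratio gate", {
  rec <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    R = c(1.40, 1.20, 0.60, 0.95, 2.0),
                    BHp = c(0.005, 0.005, 0.001, 0.001, 0.5))
  dt <- call_degs(rec)
  expect_equal(dt$records$call, c("down", "none", "up", "none", "none"))
  # b is counted ungated ("All") but not in the gated block
  expect_equal(unname(dt$counts["down_all"]), 2L)
  expect_equal(unname(dt$counts["down_gated"]), 1L)
  expect_equal(unname(dt$counts["up_all"]), 2L)
  expect_equal(unname(dt$counts["up_gated"]), 1L)
})

test_that("down/up ratios recompute from printed study counts", {
  printed <- list("D0-D123" = c(885, 526), "D123-D4i.1" = c(2383, 1622),
                  "D4i.1-D4i.2" = c(1254, 1129))
  tabs <- lapply(names(printed), function(cmp) {
    k <- printed[[cmp]]
    rec <- data.frame(gene = sprintf("g%04d", seq_len(sum(k))),
                      R = rep(c(2, 0.5), k), BHp = 0.001)
    call_degs(rec, comparison = cmp)
  })
  names(tabs) <- names(printed)
  expect_equal(deg_summary(tabs)$down_up_ratio, c(1.68, 1.47, 1.11))
})

test_that("compare_domains controls the null and recovers planted effects", {
  # null: one domain, no modules; random split into 2 x 300 cells
  cfg <- small_cfg(55, n_cells = 600, n_genes = 1500,
                   domain_props = c(D0 = 1, D1 = 0, D2 = 0, D3 = 0, D4 = 0),
                   modules = c(continuous_down = 0, continuous_up = 0,
                               d0d1_only_down = 0, d0d1_only_up = 0),
                   frac_dying = 0, frac_highcount = 0, frac_melanocyte = 0,
                   frac_langerhans = 0, frac_blood = 0, frac_conjunctival = 0)
  sim <- simulate_sample(cfg)
  nm <- normalize_to_unit_mgc(sim$cm)
  set.seed(1)
  idx <- sample(600)
  gr <- list(groups = list(A = idx[1:300], B = idx[301:600]))
  dt <- compare_domains(nm, gr, "A-B")
  expect_equal(unname(dt$counts["down_gated"] + dt$counts["up_gated"]), 0L)
  expect_lt(mean(dt$records$p < 0.01, na.rm = TRUE), 0.02)
  # planted: modules between D0 and D1 groups
  sim2 <- simulate_sample(small_cfg(56, n_cells = 2500, n_genes = 1200))
  tr <- trim_by_mgc(sim2$cm, flag_cells(sim2$cm, test_panel()))
  nm2 <- normalize_to_unit_mgc(tr$cm)
  tru <- sim2$truth$cells
  m <- match(nm2$cell_ids, tru$cell_id)
  gr2 <- list(groups = list(D0 = which(tru$domain[m] == "D0"),
                            D1 = which(tru$domain[m] == "D1")))
  dt2 <- compare_domains(nm2, gr2, "D0-D1")
  tg <- sim2$truth$genes
  planted_dn <- tg$gene_id[tg$module %in% c("continuous_down",
                                            "d0d1_only_down")]
  calls <- dt2$records$call[match(planted_dn, dt2$records$gene)]
  expect_gte(mean(calls == "down"), 0.9)
  expect_error(compare_domains(nm2, list(groups = list(A = 1:5, B = 4:9)),
                               "A-B"), "overlap")
})

test_that("halving the groups keeps ratios but inflates BHp", {
  # the half-population experiment: excluding every other cell of each
  # group leaves the well-expressed genes' ratios in place while the
  # adjusted p-values of the significant genes grow
  sim <- simulate_sample(small_cfg(57, n_cells = 4000, n_genes = 1200))
  tr <- trim_by_mgc(sim$cm, flag_cells(sim$cm, test_panel()))
  nm <- normalize_to_unit_mgc(tr$cm)
  tru <- sim$truth$cells
  m <- match(nm$cell_ids, tru$cell_id)
  d0 <- which(tru$domain[m] == "D0"); d4 <- which(tru$domain[m] == "D4")
  gr_full <- list(groups = list(A = d0, B = d4))
  gr_half <- list(groups = list(A = d0[seq_along(d0) %% 2 == 1],
                                B = d4[seq_along(d4) %% 2 == 1]))
  uni <- select_gene_universe(nm, 800)
  full <- compare_domains(nm, gr_full, "A-B", universe = uni)
  half <- compare_domains(nm, gr_half, "A-B", universe = uni)
  expressed <- full$records$mean_A > 3 & full$records$mean_B > 3
  rr <- half$records$R[expressed] / full$records$R[expressed]
  # ratios are unchanged on average (the meaningful check is the mean +/-
  # SD of the ratio-of-ratios, ~ 1.00 +/- 0.04); per-gene scatter has an
  # NB dispersion floor
  expect_lt(abs(mean(rr) - 1), 0.02)
  expect_lt(stats::sd(rr), 0.08)
  sig <- which(full$records$BHp < 0.01)
  expect_gt(stats::median(half$records$BHp[sig]),
            stats::median(full$records$BHp[sig]))
})

test_that("BHp yield decays with expression level and conserves totals", {
  # uniform planted effect: every gene shifts 1.3-fold between the groups,
  # so the per-bin significant-gene yield tracks statistical power, which
  # decays with expression level
  set.seed(58)
  n_genes <- 1200; n <- 300
  mu <- sort(rlnorm(n_genes, 0, 1.6), decreasing = TRUE)
  counts <- cbind(
    matrix(rnbinom(n_genes * n, mu = mu, size = 2), n_genes),
    matrix(rnbinom(n_genes * n, mu = mu * 1.3, size = 2), n_genes))
  ids <- sprintf("g%04d", seq_len(n_genes))
  nm <- norm_matrix(counts, ids, sprintf("c%03d", seq_len(2 * n)), n_genes)
  gr <- list(groups = list(A = 1:n, B = (n + 1):(2 * n)))
  y <- bhp_yield_by_expression(nm, gr, "A-B", n_quantiles = 6,
                               genes_per_quantile = 200)
  expect_equal(sum(y$n_signif), attr(y, "total_signif"))
  expect_gt(y$n_signif[1], y$n_signif[6])
  expect_lt(cor(y$quantile, y$n_signif, method = "spearman"), 0)
  # an all-zero bin yields nothing: zero-variance genes never reject
  expect_equal(unname(krtgauge:::.welch_rows(matrix(0, 2, 5),
                                             matrix(0, 2, 5))$p), c(1, 1))
  expect_error(bhp_yield_by_expression(nm, gr, "A-B", n_quantiles = 10,
                                       genes_per_quantile = 2000),
               "not enough")
})
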