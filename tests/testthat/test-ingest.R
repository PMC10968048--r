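test_that("CSV reader returns counts as written, preserving row order", {
  tf <- file.path(tempdir(), "tiny.csv")
  writeLines(c("gene,c1,c2", "KRT5,1,0", "KRT14,2,3", "AQP5,0,0"), tf)
  cm <- read_counts_csv(tf, probed_gene_count = 10)
  expect_equal(as.matrix(cm$counts),
               matrix(c(1, 0, 2, 3, 0, 0), 3, 2, byrow = TRUE,
                      dimnames = list(c("KRT5", "KRT14", "AQP5"),
                                      c("c1", "c2"))))
  expect_equal(cm$probed_gene_count, 10L)
})

test_that("duplicate gene symbols are disambiguated by suffix", {
  tf <- file.path(tempdir(), "dup.csv")
  writeLines(c("gene,c1", "KRT6A,1", "KRT6A,2"), tf)
  cm <- read_counts_csv(tf, 10)
  expect_equal(cm$gene_ids, c("KRT6A", "KRT6A_2"))
})

test_that("malformed CSV rows are rejected with the offending line", {
  tf <- file.path(tempdir(), "bad.csv")
  writeLines(c("gene,c1,c2", "KRT5,1,0", "KRT14,2"), tf)
  expect_error(read_counts_csv(tf, 10), "line 3")
  writeLines(c("gene,c1", "KRT5,1.5"), tf)
  expect_error(read_counts_csv(tf, 10), "non-integer")
  writeLines("gene,c1", tf)
  expect_error(read_counts_csv(tf, 10), "empty")
})

test_that("MatrixMarket reader handles sparse, empty and missing-sidecar cases", {
  d <- file.path(tempdir(), "mtx1")
  dir.create(d, showWarnings = FALSE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "2 1 5"), file.path(d, "matrix.mtx"))
  writeLines(paste(c("G1", "G2", "G3"), c("G1", "G2", "G3"), sep = "\t"),
             file.path(d, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(d, "barcodes.tsv"))
  cm <- read_counts_mtx(d, 10)
  expect_equal(unname(as.matrix(cm$counts)),
               matrix(c(0, 0, 5, 0, 0, 0), 3, 2, byrow = TRUE))
  # empty triplet list -> all-zero matrix of the declared shape
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(d, "matrix.mtx"))
  cm0 <- read_counts_mtx(d, 10)
  expect_equal(sum(cm0$counts), 0)
  expect_equal(dim(cm0$counts), c(3L, 2L))
  file.remove(file.path(d, "barcodes.tsv"))
  expect_error(read_counts_mtx(d, 10), "barcodes")
})

test_that("CSV and MatrixMarket fixtures round-trip to identical matrices", {
  sim <- simulate_sample(small_cfg(11, n_cells = 120, n_genes = 600))
  d1 <- file.path(tempdir(), "fx_csv")
  d2 <- file.path(tempdir(), "fx_mtx")
  write_fixture(sim, d1, "csv")
  write_fixture(sim, d2, "mtx")
  cm1 <- read_counts_csv(file.path(d1, "counts.csv"),
                         sim$cm$probed_gene_count)
  cm2 <- read_counts_mtx(d2, sim$cm$probed_gene_count)
  expect_equal(as.matrix(cm1$counts), as.matrix(sim$cm$counts))
  expect_identical(as.matrix(cm1$counts), as.matrix(cm2$counts))
  expect_identical(cm1$gene_ids, cm2$gene_ids)
})

test_that("marker flagging follows the and/or rule with priority order", {
  counts <- matrix(0, 6, 5,
                   dimnames = list(c("DCT", "KRT14", "KRT5", "AQP5", "TYR",
                                     "GAPDH"), paste0("c", 1:5)))
  counts["DCT", 1] <- 3; counts["KRT14", 1] <- 7   # melanocyte duplet
  counts["KRT14", 2] <- 1                           # plain epithelial
  counts["AQP5", 3] <- 2; counts["KRT5", 3] <- 4    # conjunctival
  counts["GAPDH", 4] <- 5                           # no keratin at all
  counts["TYR", 5] <- 1; counts["AQP5", 5] <- 9     # melanocyte beats conj
  cm <- count_matrix(counts, rownames(counts), colnames(counts), 10)
  fl <- suppressWarnings(flag_cells(cm, marker_panel()))
  expect_equal(fl$flag, c("melanocyte", "kept", "conjunctival",
                          "not_epithelial", "melanocyte"))
})

test_that("flagging recovers the generator's contaminant labels exactly", {
  sim <- simulate_sample(small_cfg(21, n_cells = 1500, n_genes = 800,
                                   frac_melanocyte = 0.10))
  fl <- flag_cells(sim$cm, test_panel())
  tru <- sim$truth$cells
  expected <- c(epithelial = "kept", dying = "kept", highcount = "kept",
                melanocyte = "melanocyte", duplet = "melanocyte",
                blood = "blood", langerhans = "langerhans",
                conjunctival = "conjunctival")
  expect_equal(fl$flag, unname(expected[tru$type]))
})

test_that("MGC equals column totals over probed genes", {
  counts <- matrix(rpois(40, 5), 8, 5)
  cm <- count_matrix(counts, paste0("g", 1:8), paste0("c", 1:5), 100)
  qc <- compute_mgc(cm)
  expect_equal(unname(qc$mgc), colSums(counts) / 100)
  expect_equal(qc$curve, sort(qc$mgc, decreasing = TRUE))
  # zero-count cell has MGC 0; a cell totalling probed_gene_count has MGC 1
  counts2 <- cbind(rep(0, 8), c(100, rep(0, 7)))
  cm2 <- count_matrix(counts2, paste0("g", 1:8), c("a", "b"), 100)
  expect_equal(unname(compute_mgc(cm2)$mgc), c(0, 1))
})

test_that("MGC trim uses strict bounds on both ends", {
  # engineer cells with MGC 0.4, 0.5, 0.6, 2.5, 2.6 over 10 probed genes
  tot <- c(4, 5, 6, 25, 26)
  counts <- rbind(tot, matrix(0, 4, 5))
  cm <- count_matrix(counts, paste0("g", 1:5), paste0("c", 1:5), 10)
  qc <- data.frame(cell_id = cm$cell_ids, flag = "kept",
                   stringsAsFactors = FALSE)
  tr <- trim_by_mgc(cm, qc, low = 0.5, high = 2.5)
  expect_equal(tr$cm$cell_ids, "c3")
  expect_equal(tr$qc$flag, c("low_mgc", "low_mgc", "kept", "high_mgc",
                             "high_mgc"))
  # all cells at MGC 1 are kept
  cm1 <- count_matrix(matrix(2, 5, 3), paste0("g", 1:5), paste0("c", 1:3), 10)
  qc1 <- data.frame(cell_id = cm1$cell_ids, flag = "kept")
  expect_equal(ncol(trim_by_mgc(cm1, qc1)$cm$counts), 3L)
  expect_error(trim_by_mgc(cm1, qc1, low = 3, high = 4), "no cells survive")
})

test_that("trimming matches the generator's library-scale truth exactly", {
  sim <- simulate_sample(small_cfg(31, n_cells = 1200, n_genes = 800,
                                   frac_dying = 0.15))
  fl <- flag_cells(sim$cm, test_panel())
  tr <- trim_by_mgc(sim$cm, fl)
  tru <- sim$truth$cells
  expect_setequal(tr$cm$cell_ids, tru$cell_id[tru$type == "epithelial"])
})

test_that("raising low or lowering high never enlarges the kept set", {
  sim <- simulate_sample(small_cfg(41, n_cells = 600, n_genes = 600))
  fl <- flag_cells(sim$cm, test_panel())
  kept <- function(lo, hi) trim_by_mgc(sim$cm, fl, lo, hi)$cm$cell_ids
  base <- kept(0.5, 2.5)
  expect_true(all(kept(0.7, 2.5) %in% base))
  expect_true(all(kept(0.5, 2.0) %in% base))
  expect_true(all(kept(0.8, 1.8) %in% kept(0.7, 2.0)))
})

test_that("unit-MGC normalisation conserves column totals at the probed count", {
  sim <- simulate_sample(small_cfg(51, n_cells = 400, n_genes = 600))
  fl <- flag_cells(sim$cm, test_panel())
  tr <- trim_by_mgc(sim$cm, fl)
  nm <- normalize_to_unit_mgc(tr$cm)
  tot <- as.vector(Matrix::colSums(nm$values))
  expect_true(all(abs(tot / nm$probed_gene_count - 1) < 1e-9))
  # a cell at MGC 2 has its counts halved; a cell at MGC 1 is unchanged
  counts <- cbind(c(4, 16), c(6, 4))
  cm <- count_matrix(counts, c("g1", "g2"), c("a", "b"), 10)
  nm2 <- normalize_to_unit_mgc(cm)
  expect_equal(as.numeric(nm2$values[, "a"]), c(2, 8))
  expect_equal(as.numeric(nm2$values[, "b"]), c(6, 4))
})

test_that("flags are exhaustive and exclusive: categories sum to the total", {
  sim <- simulate_sample(small_cfg(61, n_cells = 1000, n_genes = 800))
  fl <- flag_cells(sim$cm, test_panel())
  tr <- trim_by_mgc(sim$cm, fl)
  expect_equal(sum(table(tr$qc$flag)), ncol(sim$cm$counts))
  acct <- accounting(list(s1 = list(qc = tr$qc, cm = tr$cm)))
  n <- function(cat) acct$n[acct$category == cat]
  expect_equal(n("total"),
               n("melanocyte") + n("langerhans") + n("blood") +
                 n("conjunctival") + n("not_epithelial") + n("epithelial"))
  expect_equal(n("non_epithelial") + n("epithelial"), n("total"))
})

test_that("accounting reproduces printed-precision percentages", {
  # a sample shaped like the study's largest: 5843 cells, 585 melanocyte,
  # 3 Langerhans, 3 blood, 9 conjunctival; 3640 kept; 1118 gauge-negative
  flag <- rep("kept", 5843)
  flag[1:585] <- "melanocyte"
  flag[586:588] <- "langerhans"
  flag[589:591] <- "blood"
  flag[592:600] <- "conjunctival"
  flag[601:2203] <- "low_mgc"   # 5843 - 600 - 3640 = 1603 trimmed
  qc <- data.frame(cell_id = sprintf("c%04d", 1:5843), mgc = 1, flag = flag)
  kept_ids <- qc$cell_id[qc$flag == "kept"]
  counts <- rbind(c(rep(0L, 1118), rep(2L, 3640 - 1118)), rep(1L, 3640))
  cm <- count_matrix(counts, c("KRT12", "KRT5"), kept_ids, 33531)
  acct <- accounting(list("LiPe-1" = list(qc = qc, cm = cm)))
  val <- function(cat) acct$pct[acct$category == cat]
  expect_equal(val("melanocyte"), 10.01)
  expect_equal(val("epithelial"), 89.7)
  expect_equal(val("mgc_kept"), 69.4)
  expect_equal(acct$n[acct$category == "gauge_zero"], 1118)
  # a clean sample: no flags, all percents collapse to 0/100
  qc2 <- data.frame(cell_id = c("a", "b"), mgc = 1, flag = "kept")
  cm2 <- count_matrix(matrix(1, 2, 2), c("KRT12", "KRT5"), c("a", "b"), 10)
  acct2 <- accounting(list(s = list(qc = qc2, cm = cm2)))
  expect_equal(acct2$pct[acct2$category == "melanocyte"], 0)
  expect_equal(acct2$pct[acct2$category == "epithelial"], 100)
})
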