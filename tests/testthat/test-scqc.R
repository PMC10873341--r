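test_that("QC boundary semantics match the exclusion rules on the 6-cell fixture", {
  x <- qc_fixture()
  res <- qc_filter(x)
  # hand enumeration: C1 fails min_genes, C2 min_counts, C3 max_counts,
  # C4 mito; C5 clean; C6 sits exactly on every boundary and is retained
  expect_equal(res$report$n_input_cells, 6L)
  expect_equal(res$report$n_removed_min_genes, 1L)
  expect_equal(res$report$n_removed_min_counts, 1L)
  expect_equal(res$report$n_removed_max_counts, 1L)
  expect_equal(res$report$n_removed_mito, 1L)
  expect_equal(res$report$n_removed, 4L)
  expect_equal(res$report$n_retained, 2L)
  expect_setequal(res$matrix$cell_meta$barcode, c("C5", "C6"))
  expect_equal(res$report$n_input_cells,
               res$report$n_retained + res$report$n_removed)
})

test_that("QC filtering is idempotent", {
  prof <- small_profiles()
  sim <- simulate_cells(prof, c(A = 80, B = 80, C = 80), library_size = 2000,
                        seed = 9)
  r1 <- qc_filter(sim$matrix, min_counts = 1500)
  r2 <- qc_filter(r1$matrix, min_counts = 1500)
  expect_equal(r2$report$n_removed, 0L)
  expect_identical(r2$matrix$cell_meta$barcode, r1$matrix$cell_meta$barcode)
})

test_that("QC without mito genes warns and skips the mito rule", {
  m <- matrix(rpois(400 * 3, 3), nrow = 400,
              dimnames = list(sprintf("G%03d", 1:400), c("a", "b", "c")))
  expect_warning(res <- qc_filter(gexp(m)), "mito")
  expect_equal(res$report$n_removed_mito, 0L)
})

test_that("CPM normalization rescales columns and log mode maps 0 to 0", {
  m <- matrix(c(1000L, 1000L, 0L, 500L, 1000L, 500L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  norm <- normalize_cpm(m)
  expect_equal(unname(norm[, "c1"]), c(5e5, 5e5, 0))  # total 2000 -> x500
  expect_equal(unname(Matrix::colSums(norm)), c(1e6, 1e6), tolerance = 1e-9)
  logn <- normalize_cpm(m, log_transform = TRUE)
  expect_identical(logn["g3", "c1"], 0)
  zero <- m; zero[, 2] <- 0L
  expect_error(normalize_cpm(zero), "c2")
})

test_that("HVG selection finds variance-inflated genes via brute-force dispersion", {
  set.seed(21)
  n_genes <- 200; n_cells <- 400
  # graded baseline means so mean-expression bins mix gene kinds; 10 genes
  # get 20x inflated variance by construction (scaled Poisson: identical
  # mean, 20x the variance), one centered in every other mean bin
  lam <- seq(2, 20, length.out = n_genes)
  base <- matrix(rpois(n_genes * n_cells, rep(lam, n_cells)), nrow = n_genes)
  hot <- seq(5, 185, by = 20)
  base[hot, ] <- 20L * matrix(rpois(10 * n_cells, rep(lam[hot] / 20, n_cells)),
                              nrow = 10)
  dimnames(base) <- list(sprintf("G%03d", 1:n_genes), sprintf("C%03d", 1:n_cells))
  hv <- select_hvg(gexp(base), n = 10)
  expect_setequal(hv$gene, sprintf("G%03d", hot))
  # independent brute-force variance-to-mean dispersion on linear CPM
  ln <- as.matrix(normalize_cpm(base))
  disp <- unname(apply(ln, 1, var) / rowMeans(ln))
  full <- select_hvg(gexp(base), n = n_genes)
  expect_equal(unname(full$dispersion[match(rownames(base), full$gene)]),
               disp, tolerance = 1e-10)
  expect_warning(select_hvg(gexp(base), n = n_genes + 5), "returning all")
  expect_equal(nrow(select_hvg(gexp(base), n = n_genes)), n_genes)
  # constant genes (constant after normalization: equal cell totals here)
  # rank last with dispersion 0
  m2 <- matrix(c(5L, 5L, 5L, 5L,     # constant gene
                 1L, 9L, 2L, 8L,     # variable gene
                 4L, 0L, 3L, 1L,     # variable gene
                 10L, 6L, 10L, 6L),  # filler keeping totals equal
               nrow = 4, byrow = TRUE,
               dimnames = list(c("const", "v1", "v2", "fill"),
                               sprintf("c%d", 1:4)))
  stopifnot(length(unique(colSums(m2))) == 1)
  full2 <- select_hvg(gexp(m2), n = 4)
  expect_equal(unname(full2$dispersion[full2$gene == "const"]), 0)
  expect_equal(full2$gene[full2$rank == 4], "const")
})

test_that("find_markers matches the wilcox.test oracle gene by gene", {
  set.seed(31)
  n_cells <- 60
  labels <- rep(c("g1", "g2"), each = n_cells / 2)
  m <- matrix(rpois(20 * n_cells, 4), nrow = 20,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("C%02d", 1:n_cells)))
  m[1:3, labels == "g1"] <- m[1:3, labels == "g1"] + 15L
  norm <- as.matrix(normalize_cpm(m))
  res <- find_markers(normalize_cpm(m), labels, "g1", "g2",
                      min_pct = 0, report_floor_logfc = 0, report_floor_pct = 0)
  for (g in res$gene) {
    ref_p <- suppressWarnings(
      wilcox.test(norm[g, labels == "g1"], norm[g, labels == "g2"],
                  exact = FALSE, correct = TRUE))$p.value
    expect_equal(res$p_value[res$gene == g], ref_p, tolerance = 1e-9)
  }
  expect_true(all(res$passes_threshold[res$gene %in% c("G01", "G02", "G03")]))
})

test_that("a strongly shifted gene is detected with the expected fold change", {
  prof <- small_profiles(effect = 8)
  sim <- simulate_cells(prof, c(A = 200, B = 200, C = 50), seed = 41)
  res <- find_markers(sim$matrix, group1 = "A", group2 = "B")
  mk <- prof$marker_map$A
  hits <- res |> dplyr::filter(.data$gene %in% mk)
  expect_gt(nrow(hits), 25)
  expect_true(all(hits$passes_threshold))
  expect_equal(median(hits$log2_fold_change), 3, tolerance = 0.25)
  expect_true(all(hits$p_adjusted < 0.05))
})

test_that("null genes are not flagged and low-detection genes are excluded", {
  set.seed(51)
  n_cells <- 200
  labels <- rep(c("g1", "g2"), each = 100)
  m <- matrix(rpois(50 * n_cells, 4), nrow = 50,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("C%03d", 1:n_cells)))
  # gene detected in ~5% of cells in both groups
  m[50, ] <- 0L
  m[50, sample(n_cells, 10)] <- 5L
  res <- find_markers(normalize_cpm(m), labels, "g1", "g2", min_pct = 0.1)
  expect_false("G50" %in% res$gene)
  expect_false(any(res$passes_threshold))
})

test_that("log2FC is antisymmetric and BH matches the brute-force oracle", {
  set.seed(61)
  labels <- rep(c("g1", "g2"), each = 40)
  m <- matrix(rpois(30 * 80, 3), nrow = 30,
              dimnames = list(sprintf("G%02d", 1:30), sprintf("C%02d", 1:80)))
  m[1:5, labels == "g1"] <- m[1:5, labels == "g1"] + 6L
  norm <- normalize_cpm(m)
  a <- find_markers(norm, labels, "g1", "g2", min_pct = 0,
                    report_floor_logfc = 0, report_floor_pct = 0)
  b <- find_markers(norm, labels, "g2", "g1", min_pct = 0,
                    report_floor_logfc = 0, report_floor_pct = 0)
  j <- dplyr::inner_join(a, b, by = "gene")
  expect_equal(j$log2_fold_change.x, -j$log2_fold_change.y, tolerance = 1e-9)
  expect_equal(a$p_adjusted, bh_oracle(a$p_value), tolerance = 1e-12)
  expect_true(all(diff(a$p_adjusted[order(a$p_value)]) >= -1e-12))
})

test_that("degenerate group specifications error", {
  m <- matrix(rpois(40, 4), nrow = 10,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("C%d", 1:4)))
  labels <- c("a", "a", "b", "b")
  expect_error(find_markers(normalize_cpm(m), labels, c("a", "b"), "b"), "overlap")
  expect_error(find_markers(normalize_cpm(m), labels, "a", "c"), "non-empty")
  expect_error(
    find_markers(normalize_cpm(m), c("a", "b", "b", "b"), "a", "b"), "size 1")
})
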