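#' Quality-control filter for single cells
#'
#' Removes cells expressing fewer than `min_genes` genes, with total
#' counts falling below `min_counts` or exceeding `max_counts`, or with a
#' mitochondrial fraction exceeding `max_mito`. All exclusions are
#' strict, so a cell sitting exactly on a boundary is retained.
#' Mitochondrial genes are identified by the `MT-` name prefix recorded
#' in the container; when no such gene exists the mito rule is skipped
#' with a warning.
#'
#' @param x A [gexp] object.
#' @param min_genes Minimum detected genes (cell removed if fewer).
#' @param min_counts,max_counts Total-count window (removed if below /
#'   above).
#' @param max_mito Maximum mitochondrial fraction (removed if exceeding).
#'
#' @return List with `matrix` (filtered [gexp]) and `report` (a
#'   `qc_report` tibble wrapper: n_input_cells, per-rule removal counts —
#'   overlapping —, n_removed, n_retained; `n_removed_doublets` is a
#'   placeholder, always 0, since doublet detection is out of scope).
#' @export
qc_filter <- function(x, min_genes = 300, min_counts = 500,
                      max_counts = 30000, max_mito = 0.10) {
  stopifnot(inherits(x, "gexp"))
  if (ncol(x$counts) == 0) abort("empty matrix: no cells to filter.")
  if (min_genes <= 0 || min_counts <= 0 || max_counts <= 0 || max_mito <= 0) {
    abort("QC thresholds must be positive.")
  }
  m <- x$cell_meta
  fail_genes <- m$n_genes_detected < min_genes
  fail_low <- m$total_counts < min_counts
  fail_high <- m$total_counts > max_counts
  if (all(is.na(m$mito_fraction))) {
    warn("no mitochondrial (MT-) genes found; mito rule skipped.")
    fail_mito <- rep(FALSE, nrow(m))
  } else {
    fail_mito <- m$mito_fraction > max_mito
  }
  fail_any <- fail_genes | fail_low | fail_high | fail_mito
  report <- structure(
    tibble(n_input_cells = nrow(m),
           n_removed_min_genes = sum(fail_genes),
           n_removed_min_counts = sum(fail_low),
           n_removed_max_counts = sum(fail_high),
           n_removed_mito = sum(fail_mito),
           n_removed_doublets = 0L,
           n_removed = sum(fail_any),
           n_retained = sum(!fail_any)),
    class = c("qc_report", "tbl_df", "tbl", "data.frame"))
  list(matrix = gexp_subset_cells(x, m$barcode[!fail_any]), report = report)
}

#' Counts-per-scale normalization
#'
#' Rescales each cell (column) to a fixed total, optionally followed by
#' log2(x + 1). No gene-length correction: UMI counts have no length
#' bias; bulk inputs enter the pipeline already as TPM.
#'
#' @param x A [gexp] object or genes x cells (sparse) matrix.
#' @param scale Target column total (default 1e6, i.e. CPM).
#' @param log_transform If `TRUE`, return log2(normalized + 1).
#'
#' @return A `dgCMatrix` of normalized values, same dimnames as input.
#' @export
normalize_cpm <- function(x, scale = 1e6, log_transform = FALSE) {
  counts <- if (inherits(x, "gexp")) x$counts else x
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    abort(paste0("cells with zero total counts: ",
                 paste(head(colnames(counts)[tot == 0], 5), collapse = ", ")))
  }
  out <- counts %*% Matrix::Diagonal(x = scale / tot)
  dimnames(out) <- dimnames(counts)
  if (log_transform) out@x <- log2(out@x + 1)
  methods::as(out, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion of normalized expression, the
#' mean/variance-plot convention: dispersion is the variance-to-mean
#' ratio of linear CPM (log-transformed for symmetry), z-scored within
#' 20 equal-frequency mean-expression bins so that highly expressed
#' genes are not favored merely for their scale. Deterministic; ties
#' broken by raw dispersion, then gene order. Constant genes have
#' dispersion 0 and rank last.
#'
#' @param x A [gexp] object or genes x cells matrix of raw counts.
#' @param n Number of genes to return (default 3000).
#' @param n_bins Mean-expression bins for standardization.
#'
#' @return Tibble: gene, mean (linear CPM), dispersion (variance/mean),
#'   dispersion_standardized, rank — the top `n` in rank order.
#' @export
select_hvg <- function(x, n = 3000, n_bins = 20) {
  if (n < 1) abort("`n` must be >= 1.")
  norm <- normalize_cpm(x)
  mu <- Matrix::rowMeans(norm)
  v <- rowVars_sparse(norm)
  disp <- ifelse(mu > 0 & v > 0, v / mu, 0)
  n_genes <- length(mu)
  if (n > n_genes) {
    warn(sprintf("requested %d HVGs from %d genes; returning all.", n, n_genes))
    n <- n_genes
  }
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, n_genes), labels = FALSE)
  ldisp <- ifelse(disp > 0, log(disp), 0)
  zs <- stats::ave(ldisp, bins, FUN = function(d) {
    s <- sd(d)
    if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  })
  zs[disp == 0] <- -Inf  # constant genes always rank last
  ord <- order(-zs, -disp, seq_along(zs))
  tibble(gene = rownames(norm)[ord],
         mean = mu[ord], dispersion = disp[ord],
         dispersion_standardized = zs[ord],
         rank = seq_along(ord))[seq_len(n), ]
}

# row variances of a sparse matrix without densifying
rowVars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  sq <- Matrix::rowMeans(m^2)
  nc <- ncol(m)
  pmax(0, (sq - mu^2) * nc / max(1, nc - 1))
}

# Vectorized two-group Wilcoxon rank-sum test (normal approximation with
# tie correction and continuity correction, matching stats::wilcox.test
# defaults) applied row-wise to a genes x cells matrix.
wilcox_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); N <- n1 + n2
  sub <- as.matrix(mat[, c(idx1, idx2), drop = FALSE])
  p <- apply(sub, 1, function(v) {
    r <- rank(v)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- rle(sort(v))$lengths
    tie_term <- sum(nt^3 - nt)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- W - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  })
  unname(p)
}

#' Two-group differential expression (Wilcoxon rank-sum)
#'
#' Per-gene Wilcoxon rank-sum test on linear CPM-normalized expression
#' between two cell groups, with Benjamini-Hochberg correction across the
#' genes actually tested. Genes are excluded from testing when detected
#' in neither group above `min_pct` or when their |log2 fold change|
#' falls below `report_floor_logfc` (the reporting floor). Fold change is
#' log2((mean1 + eps) / (mean2 + eps)) on linear normalized expression,
#' eps = 1e-9.
#'
#' @param x A [gexp] object (counts are normalized internally) or a
#'   genes x cells matrix of linear normalized expression.
#' @param labels Per-cell labels, length ncol; or `NULL` to use
#'   `cell_meta$label` of a `gexp`.
#' @param group1,group2 Label values defining the two groups. `group2`
#'   may be `"rest"` to mean all cells not in `group1`.
#' @param logfc_min Significance threshold on log2FC (default 0.58, i.e.
#'   FC > 1.5; use 0.26 for FC > 1.2 cross-population comparisons).
#' @param min_pct Detection-fraction threshold: a gene must be detected
#'   in more than this fraction of cells in at least one group, both to
#'   be tested and to be flagged.
#' @param alpha Adjusted-p significance level.
#' @param report_floor_logfc,report_floor_pct Reporting floors below
#'   which genes are dropped before testing.
#'
#' @return A `deg_table` tibble: gene, log2_fold_change, pct_group1,
#'   pct_group2, p_value, p_adjusted, passes_threshold. Only tested
#'   genes appear.
#' @export
find_markers <- function(x, labels = NULL, group1, group2 = "rest",
                         logfc_min = 0.58, min_pct = 0.1, alpha = 0.05,
                         report_floor_logfc = 0.01, report_floor_pct = 0.01) {
  if (inherits(x, "gexp")) {
    if (is.null(labels)) labels <- x$cell_meta$label
    norm <- normalize_cpm(x)
  } else {
    norm <- x
  }
  if (length(labels) != ncol(norm)) abort("`labels` must have one entry per cell.")
  idx1 <- which(labels %in% group1)
  idx2 <- if (identical(group2, "rest")) setdiff(seq_along(labels), idx1)
          else which(labels %in% group2)
  if (length(intersect(idx1, idx2)) > 0) abort("groups overlap.")
  if (length(idx1) == 0 || length(idx2) == 0) abort("both groups must be non-empty.")
  if (length(idx1) < 2 || length(idx2) < 2) {
    abort("groups of size 1 are not testable with a rank-sum test.")
  }

  m1 <- Matrix::rowMeans(norm[, idx1, drop = FALSE])
  m2 <- Matrix::rowMeans(norm[, idx2, drop = FALSE])
  pct1 <- Matrix::rowMeans(norm[, idx1, drop = FALSE] > 0)
  pct2 <- Matrix::rowMeans(norm[, idx2, drop = FALSE] > 0)
  eps <- 1e-9
  lfc <- log2((m1 + eps) / (m2 + eps))

  tested <- (pmax(pct1, pct2) > min_pct) &
    (pmax(pct1, pct2) >= report_floor_pct) &
    (abs(lfc) >= report_floor_logfc)
  if (!any(tested)) {
    return(structure(tibble(gene = character(), log2_fold_change = double(),
                            pct_group1 = double(), pct_group2 = double(),
                            p_value = double(), p_adjusted = double(),
                            passes_threshold = logical()),
                     class = c("deg_table", "tbl_df", "tbl", "data.frame")))
  }
  p <- wilcox_rows(norm[tested, , drop = FALSE], idx1, idx2)
  padj <- p.adjust(p, method = "BH")
  out <- tibble(gene = rownames(norm)[tested],
                log2_fold_change = lfc[tested],
                pct_group1 = pct1[tested], pct_group2 = pct2[tested],
                p_value = p, p_adjusted = padj) |>
    mutate(passes_threshold = .data$log2_fold_change > logfc_min &
             pmax(.data$pct_group1, .data$pct_group2) > min_pct &
             .data$p_adjusted < alpha) |>
    arrange(.data$p_adjusted, .data$p_value, dplyr::desc(.data$log2_fold_change))
  structure(out, class = c("deg_table", class(out)))
}
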