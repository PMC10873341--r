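#' Gene-by-cell expression container
#'
#' A light container for a genes-by-cells count matrix plus a per-cell
#' metadata tibble. Counts are held sparse (`dgCMatrix`); rows are genes,
#' columns are cells, matching the orientation of droplet-pipeline MTX
#' output. Per-cell QC covariates (`n_genes_detected`, `total_counts`,
#' `mito_fraction`) are derived from the counts at construction time and
#' kept in sync by every operation that subsets cells.
#'
#' @param counts Non-negative integer matrix or sparse Matrix, genes x cells,
#'   with unique rownames (gene ids) and colnames (cell barcodes).
#' @param cell_meta Optional tibble with one row per cell. Must contain a
#'   `barcode` column matching `colnames(counts)`; typically also carries
#'   `sample_id` and a ground-truth or assigned `label`.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes
#'   (default `"MT-"`), used to derive `mito_fraction`.
#'
#' @return An object of class `gexp` with elements `counts` (dgCMatrix) and
#'   `cell_meta` (tibble).
#' @export
gexp <- function(counts, cell_meta = NULL, mito_prefix = "MT-") {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs gene rownames and cell colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("gene ids must be unique.")
  if (anyDuplicated(colnames(counts))) abort("cell barcodes must be unique.")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) abort("`counts` must be non-negative.")
  if (any(counts@x != round(counts@x))) abort("`counts` must be integral.")

  meta <- if (is.null(cell_meta)) {
    tibble(barcode = colnames(counts))
  } else {
    cell_meta <- as_tibble(cell_meta)
    if (!"barcode" %in% names(cell_meta)) abort("`cell_meta` needs a `barcode` column.")
    if (!setequal(cell_meta$barcode, colnames(counts))) {
      abort("`cell_meta$barcode` must match colnames(counts).")
    }
    cell_meta[match(colnames(counts), cell_meta$barcode), ]
  }

  mito <- startsWith(rownames(counts), mito_prefix)
  tot <- Matrix::colSums(counts)
  meta$n_genes_detected <- Matrix::colSums(counts > 0)
  meta$total_counts <- tot
  meta$mito_fraction <- if (any(mito)) {
    ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1), 0)
  } else {
    NA_real_
  }
  structure(list(counts = counts, cell_meta = meta, mito_prefix = mito_prefix),
            class = "gexp")
}

#' @export
print.gexp <- function(x, ...) {
  cat(sprintf("<gexp> %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  if ("label" %in% names(x$cell_meta)) {
    tab <- table(x$cell_meta$label)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.gexp <- function(x) dim(x$counts)

#' Subset a gexp by cells
#'
#' @param x A [gexp] object.
#' @param barcodes Character vector of barcodes to keep.
#' @return A `gexp` restricted to those cells (derived QC columns recomputed).
#' @export
gexp_subset_cells <- function(x, barcodes) {
  stopifnot(inherits(x, "gexp"))
  keep <- colnames(x$counts) %in% barcodes
  gexp(x$counts[, keep, drop = FALSE],
       x$cell_meta[x$cell_meta$barcode %in% barcodes,
                   setdiff(names(x$cell_meta),
                           c("n_genes_detected", "total_counts", "mito_fraction"))],
       mito_prefix = x$mito_prefix)
}
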