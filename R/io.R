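#' Read and write standard formats
#'
#' Genes are rows in every matrix format. MTX triplets travel with
#' `genes.tsv` / `barcodes.tsv` sidecars; dense matrices are TSV with a
#' header row of sample/cell ids and the gene id in the first column;
#' FASTQ carries the cell barcode and UMI in the read name as
#' `..._CB:<barcode>_UMI:<umi>`.
#'
#' @name io
NULL

#' @describeIn io Write a sparse genes x cells matrix as MatrixMarket MTX
#'   plus `genes.tsv` and `barcodes.tsv` in `dir`.
#' @param x Matrix (sparse or dense) with dimnames, or a [gexp].
#' @param dir Output directory (created if needed).
#' @return `write_mtx`: the directory, invisibly.
#' @export
write_mtx <- function(x, dir) {
  counts <- if (inherits(x, "gexp")) x$counts else Matrix::Matrix(x, sparse = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = rownames(counts)),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(dir)
}

#' @describeIn io Read an MTX triplet directory back into a sparse matrix.
#' @return `read_mtx`: a `dgCMatrix` with gene rownames and barcode
#'   colnames.
#' @export
read_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), col_names = "gene",
                           show_col_types = FALSE)$gene
  bcs <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "barcode",
                         show_col_types = FALSE)$barcode
  if (nrow(m) != length(genes) || ncol(m) != length(bcs)) {
    abort(sprintf("MTX dimensions (%d x %d) disagree with sidecars (%d genes, %d barcodes).",
                  nrow(m), ncol(m), length(genes), length(bcs)))
  }
  dimnames(m) <- list(genes, bcs)
  m
}

#' @describeIn io Write a dense genes x samples matrix as TSV (first
#'   column `gene`).
#' @param path File path.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- as.matrix(x)
  readr::write_tsv(bind_cols(tibble(gene = rownames(m)), as_tibble(m)), path)
  invisible(path)
}

#' @describeIn io Read a dense genes x samples TSV written by
#'   [write_matrix_tsv()]. Ragged rows are a parse error naming the row.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readr::read_lines(path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nfield)) > 1) {
    bad <- which(nfield != nfield[1])[1]
    abort(sprintf("ragged TSV: row %d has %d fields, expected %d.",
                  bad, nfield[bad], nfield[1]))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @describeIn io Write tagged reads as FASTQ (gzip if the path ends in
#'   `.gz`); barcode and UMI are appended to the read name.
#' @param reads Tibble with read_id, sequence, barcode, umi.
#' @export
write_tagged_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- sprintf("%s_CB:%s_UMI:%s", reads$read_id, reads$barcode, reads$umi)
  qual <- Biostrings::BStringSet(vapply(nchar(reads$sequence),
                                        function(n) strrep("I", n), ""))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              compress = endsWith(path, ".gz"), qualities = qual)
  invisible(path)
}

#' @describeIn io Read a (possibly gzipped) FASTQ with `_CB:`/`_UMI:`
#'   name tags back into a read tibble; reads without tags get NA
#'   barcode/umi (and are skipped downstream by [scan_reads()]).
#' @export
read_tagged_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- names(seqs)
  bc <- stringr::str_match(nm, "_CB:([^_\\s]+)")[, 2]
  umi <- stringr::str_match(nm, "_UMI:([^_\\s]+)")[, 2]
  tibble(read_id = sub("_CB:.*$", "", nm),
         sequence = unname(as.character(seqs)), barcode = bc, umi = umi)
}

#' @describeIn io Write a survival table (sample_id, time, event, and any
#'   extra columns) as TSV.
#' @export
write_survival_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @describeIn io Read a survival TSV back.
#' @export
read_survival_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @describeIn io Serialize a pipeline configuration (or any list of
#'   settings) as JSON; round-trips losslessly.
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @describeIn io Read a JSON configuration.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
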