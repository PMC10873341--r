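#' Build a joint reference/query embedding
#'
#' Puts reference and query cells into one PCA space anchored on the
#' reference: highly variable genes are chosen on the reference, both
#' sets are log-CPM normalized, every gene is centered and scaled with
#' the *reference* mean and standard deviation, the principal directions
#' are computed from the reference alone, and query cells are projected
#' onto them. A query cell with counts identical to a reference cell
#' therefore lands on identical coordinates.
#'
#' @param reference A [gexp] with labels in `cell_meta$label`.
#' @param query A [gexp] sharing the reference's gene namespace.
#' @param n_hvg Highly variable genes selected on the reference.
#' @param n_dims Number of principal components kept.
#'
#' @return A `joint_embedding`: list with `coordinates` (tibble cell_id,
#'   origin, PC1..PCn), `n_dims`, `hvg_used`, `reference_labels`
#'   (tibble cell_id, label).
#' @export
build_joint_embedding <- function(reference, query, n_hvg = 3000, n_dims = 30) {
  stopifnot(inherits(reference, "gexp"), inherits(query, "gexp"))
  shared <- intersect(rownames(reference$counts), rownames(query$counts))
  if (length(shared) == 0) abort("reference and query share no genes.")
  n_cells <- ncol(reference$counts) + ncol(query$counts)
  if (n_cells < n_dims + 1) abort("need at least n_dims + 1 cells overall.")
  if (is.null(reference$cell_meta$label)) abort("reference must carry labels.")

  hvg <- select_hvg(reference, n = min(n_hvg, length(shared)))$gene
  hvg <- intersect(hvg, shared)
  ref_ln <- as.matrix(normalize_cpm(reference, log_transform = TRUE)[hvg, , drop = FALSE])
  qry_ln <- as.matrix(normalize_cpm(query, log_transform = TRUE)[hvg, , drop = FALSE])

  mu <- rowMeans(ref_ln)
  sdv <- apply(ref_ln, 1, sd)
  sdv[sdv == 0] <- 1  # constant genes contribute nothing after centering
  ref_std <- (ref_ln - mu) / sdv
  qry_std <- (qry_ln - mu) / sdv

  n_dims <- min(n_dims, ncol(ref_ln) - 1, length(hvg))
  pc <- prcomp(t(ref_std), center = FALSE, scale. = FALSE, rank. = n_dims)
  ref_coord <- pc$x[, seq_len(n_dims), drop = FALSE]
  qry_coord <- t(qry_std) %*% pc$rotation[, seq_len(n_dims), drop = FALSE]

  coords <- bind_rows(
    bind_cols(tibble(cell_id = colnames(reference$counts), origin = "reference"),
              as_tibble(ref_coord)),
    bind_cols(tibble(cell_id = colnames(query$counts), origin = "query"),
              as_tibble(qry_coord)))
  structure(list(coordinates = coords, n_dims = n_dims, hvg_used = hvg,
                 reference_labels = tibble(cell_id = colnames(reference$counts),
                                           label = reference$cell_meta$label)),
            class = "joint_embedding")
}

#' @export
print.joint_embedding <- function(x, ...) {
  cat(sprintf("<joint_embedding> %d cells (%d reference, %d query), %d dims, %d HVGs\n",
              nrow(x$coordinates), sum(x$coordinates$origin == "reference"),
              sum(x$coordinates$origin == "query"), x$n_dims, length(x$hvg_used)))
  invisible(x)
}

#' KNN label transfer
#'
#' Labels each query cell by majority vote among its `k` Euclidean
#' nearest *reference* cells in the joint embedding. Ties on vote count
#' are broken by the smaller mean distance to the tied label's
#' neighbors, then lexicographically, so the result is deterministic and
#' order-independent.
#'
#' @param embedding A [build_joint_embedding()] result.
#' @param reference_labels Optional tibble (cell_id, label) overriding
#'   the labels stored in the embedding.
#' @param k Number of neighbors (default 50).
#'
#' @return A `label_transfer` tibble: cell_id, predicted_label,
#'   vote_fraction, mean_neighbor_distance, neighbor_ids (list-column).
#' @export
knn_transfer <- function(embedding, reference_labels = NULL, k = 50) {
  stopifnot(inherits(embedding, "joint_embedding"))
  if (k <= 0) abort("`k` must be positive.")
  labs <- reference_labels %||% embedding$reference_labels
  co <- embedding$coordinates
  pc_cols <- grep("^PC", names(co), value = TRUE)
  ref <- co[co$origin == "reference", ]
  qry <- co[co$origin == "query", ]
  if (k > nrow(ref)) abort("`k` exceeds the number of reference cells.")
  R <- as.matrix(ref[, pc_cols]); Q <- as.matrix(qry[, pc_cols])
  ref_lab <- labs$label[match(ref$cell_id, labs$cell_id)]

  # squared Euclidean distances query x reference via the expansion trick
  d2 <- outer(rowSums(Q^2), rowSums(R^2), "+") - 2 * Q %*% t(R)
  d2[d2 < 0] <- 0

  res <- map(seq_len(nrow(Q)), function(i) {
    ord <- order(d2[i, ], ref$cell_id)[seq_len(k)]
    nl <- ref_lab[ord]
    nd <- sqrt(d2[i, ord])
    votes <- sort(table(nl), decreasing = TRUE)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(l) mean(nd[nl == l]), 0)
      top <- top[order(mean_d, top)]
    }
    tibble(cell_id = qry$cell_id[i], predicted_label = top[1],
           vote_fraction = unname(max(votes)) / k,
           mean_neighbor_distance = mean(nd),
           neighbor_ids = list(ref$cell_id[ord]))
  })
  out <- bind_rows(res)
  structure(out, class = c("label_transfer", class(out)))
}
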