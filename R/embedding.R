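#' Principal-component embedding of cells
#'
#' PCA of cells in gene space with gene-wise centering and no scaling;
#' components come from the eigendecomposition of the cell covariance (via
#' SVD). Works identically on normalized values and on a binary matrix
#' treated as reals, which is how binary and count embeddings are compared
#' side by side. Sign convention: each component is flipped so that its
#' largest-magnitude gene loading is positive, making outputs reproducible.
#'
#' @param m a \code{normalized_matrix}, \code{binary_matrix} or
#'   \code{count_matrix}.
#' @param n_components number of components requested; truncated to the
#'   numerical rank with a warning when larger.
#' @return An \code{embedding}: list with \code{coords} (cells x k),
#'   \code{method}, \code{n_components}, \code{explained} (eigenvalues,
#'   non-increasing), \code{cell_ids}.
#' @export
pca_embed <- function(m, n_components = 10) {
  stopifnot(n_components >= 1)
  vals <- m$values
  if (ncol(vals) < 2) stop("need at least 2 cells")
  method <- if (inherits(m, "binary_matrix")) "pca_binary" else "pca_counts"
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- n_components
  if (k > rank) {
    warning("n_components (", k, ") exceeds rank (", rank, "); truncated")
    k <- rank
  }
  coords <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) coords[, j] <- -coords[, j]
  }
  new_embedding(coords, method, k, ev[seq_len(k)], m$cell_ids)
}

new_embedding <- function(coords, method, k, explained, cell_ids) {
  rownames(coords) <- cell_ids
  structure(list(coords = coords, method = method, n_components = k,
                 explained = explained, cell_ids = cell_ids),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding (%s): %d cells x %d components\n",
              x$method, nrow(x$coords), x$n_components))
  invisible(x)
}

#' Jaccard cell-cell similarity matrix
#'
#' S[i, j] = |detected_i intersect detected_j| / |detected_i union detected_j|
#' over the gene sets detected in each pair of cells. Symmetric with unit
#' diagonal; entries in [0, 1].
#'
#' @param b a \code{binary_matrix}; every cell must detect at least one gene.
#' @return A cells x cells similarity matrix.
#' @export
jaccard_similarity <- function(b) {
  b <- binarize(b)
  nd <- colSums(b$values)
  if (any(nd == 0))
    stop("cells with zero detected genes (Jaccard undefined); remove: ",
         paste(head(b$cell_ids[nd == 0], 5), collapse = ", "))
  inter <- crossprod(b$values)
  uni <- outer(nd, nd, `+`) - inter
  S <- inter / uni
  dimnames(S) <- list(b$cell_ids, b$cell_ids)
  S
}

#' Eigenvector embedding of the Jaccard similarity matrix
#'
#' The top-k eigenvectors of the Jaccard cell-cell similarity matrix, each
#' scaled by the square root of its eigenvalue (negative eigenvalues
#' truncated to zero), with the same sign convention as
#' \code{\link{pca_embed}}. A binary-native alternative to PCA.
#'
#' @param b a \code{binary_matrix}.
#' @param n_components number of components.
#' @return An \code{embedding} with method \code{"jaccard_eig"}.
#' @export
jaccard_eigenmap <- function(b, n_components = 10) {
  stopifnot(n_components >= 1)
  b <- binarize(b)
  S <- jaccard_similarity(b)
  k <- min(n_components, ncol(S))
  if (k < n_components)
    warning("n_components truncated to the number of cells (", k, ")")
  es <- eigen(S, symmetric = TRUE)
  lam <- pmax(es$values[seq_len(k)], 0)
  vec <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- sweep(vec, 2, sqrt(lam), `*`)
  new_embedding(coords, "jaccard_eig", k, es$values[seq_len(k)], b$cell_ids)
}

#' k-nearest-neighbor graph from an embedding
#'
#' Euclidean kNN with self excluded; ties broken by lower cell index so the
#' graph is deterministic.
#'
#' @param e an \code{embedding}.
#' @param k neighbors per cell; must be positive and below the cell count.
#' @return A \code{neighbor_graph}: \code{neighbor_ids} (cells x k integer
#'   indices) and \code{distances} (cells x k, non-decreasing per row).
#' @export
knn_graph <- function(e, k) {
  if (k <= 0) stop("k must be positive")
  n <- nrow(e$coords)
  if (k >= n) stop("k must be below the number of cells")
  D <- as.matrix(stats::dist(e$coords))
  ids <- matrix(0L, n, k)
  dd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))  # tie-break by lower index
    ids[i, ] <- ord[seq_len(k)]
    dd[i, ] <- d[ord[seq_len(k)]]
  }
  structure(list(neighbor_ids = ids, distances = dd, k = k,
                 cell_ids = e$cell_ids),
            class = "neighbor_graph")
}

#' Mean silhouette by label
#'
#' Standard silhouette s = (b - a) / max(a, b) per cell on Euclidean
#' distances, where a is the mean distance to the cell's own label and b the
#' smallest mean distance to another label. Cells in singleton clusters get
#' s = 0.
#'
#' @param e an \code{embedding}.
#' @param labels one label per cell; at least two distinct labels.
#' @return List with \code{per_cell}, \code{per_label} (named means) and
#'   \code{overall} mean silhouette.
#' @export
silhouette_by_label <- function(e, labels) {
  labels <- as.character(labels)
  n <- nrow(e$coords)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2) stop("need at least two distinct labels")
  D <- as.matrix(stats::dist(e$coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }  # singleton convention
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  per_label <- vapply(split(s, labels), mean, numeric(1))
  list(per_cell = s, per_label = per_label, overall = mean(s))
}

#' Simplified iLISI batch-mixing score
#'
#' For each cell, the proportions of batch labels among its k Euclidean
#' nearest neighbors (self excluded) give an inverse Simpson index
#' 1 / sum(proportions^2); the mean over cells is returned. 1 means no
#' mixing, the number of batches means perfect mixing. This is a fixed-k
#' simplification of the perplexity-weighted LISI.
#'
#' @param e an \code{embedding}.
#' @param batch_labels one batch label per cell; at least two batches.
#' @param k neighborhood size.
#' @return Mean inverse Simpson index in [1, n_batches].
#' @export
ilisi <- function(e, batch_labels, k = 30) {
  if (k <= 0) stop("k must be positive")
  batch_labels <- as.character(batch_labels)
  stopifnot(length(batch_labels) == nrow(e$coords))
  if (length(unique(batch_labels)) < 2) stop("need at least two batches")
  g <- knn_graph(e, k)
  scores <- apply(g$neighbor_ids, 1, function(nb) {
    pr <- table(batch_labels[nb]) / length(nb)
    1 / sum(pr^2)
  })
  mean(scores)
}

#' Correlation of pairwise cell distances between two embeddings
#'
#' Pearson correlation of the two condensed (upper-triangle) Euclidean
#' distance vectors; invariant to isometries of either embedding. Used to
#' compare binary-derived and count-derived embeddings.
#'
#' @param a,b \code{embedding}s over the same cells in the same order.
#' @return Pearson correlation.
#' @export
distance_correlation <- function(a, b) {
  if (nrow(a$coords) != nrow(b$coords))
    stop("embeddings must cover the same cells")
  da <- as.vector(stats::dist(a$coords))
  db <- as.vector(stats::dist(b$coords))
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stop("constant distance vector: correlation undefined")
  stats::cor(da, db)
}

#' Write / read an embedding as TSV
#'
#' TSV with a \code{cell_id} column followed by one column per component;
#' lets externally produced embeddings (e.g. a UMAP) be compared with
#' \code{\link{distance_correlation}}.
#'
#' @param e an \code{embedding}.
#' @param path TSV path.
#' @return \code{write_embedding_tsv}: invisibly the path;
#'   \code{read_embedding_tsv}: an \code{embedding} with method
#'   \code{"external"}.
#' @export
write_embedding_tsv <- function(e, path) {
  df <- data.frame(cell_id = e$cell_ids, e$coords, check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("comp", seq_len(ncol(e$coords))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  new_embedding(coords, "external", ncol(coords), rep(NA_real_, ncol(coords)),
                df$cell_id)
}
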