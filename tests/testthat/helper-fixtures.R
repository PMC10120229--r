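# Shared fixture builders and independent oracles.

random_count_matrix <- function(G = 10, C = 8, lambda = 1, seed = 1) {
  set.seed(seed)
  count_matrix(matrix(rpois(G * C, lambda), G, C),
               paste0("g", seq_len(G)), paste0("c", seq_len(C)))
}

random_binary_matrix <- function(G = 10, C = 8, p = 0.4, seed = 1) {
  set.seed(seed)
  binary_matrix(matrix(rbinom(G * C, 1, p), G, C),
                paste0("g", seq_len(G)), paste0("c", seq_len(C)))
}

# Two populations with disjoint detected gene sets plus shared genes.
two_pop_binary <- function(n_per = 10) {
  a_block <- matrix(1, 5, n_per)
  z_block <- matrix(0, 5, n_per)
  shared <- matrix(1, 2, 2 * n_per)
  vals <- rbind(cbind(a_block, z_block), cbind(z_block, a_block), shared)
  binary_matrix(vals, paste0("g", seq_len(nrow(vals))),
                paste0("c", seq_len(2 * n_per)))
}

# Brute-force two-sided Fisher p by full enumeration of tables with the
# observed margins, probability-ordering definition (independent of
# fisher.test internals).
fisher_p_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Dense eigendecomposition PCA oracle: covariance of cells in gene space.
pca_oracle <- function(vals, k) {
  X <- t(vals)
  X <- sweep(X, 2, colMeans(X))
  es <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  scores <- X %*% es$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores, values = es$values[seq_len(k)])
}

# Wrap raw coordinates as an embedding object.
new_emb <- function(coords) {
  structure(list(coords = coords, method = "external",
                 n_components = ncol(coords),
                 explained = rep(NA_real_, ncol(coords)),
                 cell_ids = paste0("c", seq_len(nrow(coords)))),
            class = "embedding")
}

# Brute-force kNN by scanning all pairs.
knn_oracle <- function(coords, k) {
  n <- nrow(coords)
  ids <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(coords, 2, coords[i, ])^2))
    d[i] <- Inf
    ids[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  ids
}
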