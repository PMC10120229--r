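#' Recover relative expression from neighborhood detection patterns
#'
#' Genes that are highly expressed in a neighborhood of similar cells are
#' detected in most of those cells; lowly expressed genes in few. The
#' neighborhood detection rate therefore recovers a relative expression
#' level for each gene in each cell from the binary pattern alone:
#' value(gene, cell) = fraction of the cell's k neighbors (plus the cell
#' itself when \code{include_self}) that detect the gene.
#'
#' @param b a \code{binary_matrix}.
#' @param g a \code{neighbor_graph} over the same cells (typically built on
#'   a \code{\link{jaccard_eigenmap}} embedding so the pipeline stays
#'   binary-only).
#' @param include_self count the cell's own detection in the neighborhood
#'   (default FALSE).
#' @return A \code{recovered_matrix}: \code{values} (genes x cells in
#'   [0, 1]) and \code{k_used}.
#' @export
recover_expression <- function(b, g, include_self = FALSE) {
  b <- binarize(b)
  stopifnot(inherits(g, "neighbor_graph"))
  if (g$k == 0) stop("neighbor graph has k = 0")
  n <- ncol(b$values)
  if (nrow(g$neighbor_ids) != n)
    stop("neighbor graph does not match the matrix's cells")
  vals <- matrix(0, nrow(b$values), n, dimnames = dimnames(b$values))
  for (i in seq_len(n)) {
    nb <- g$neighbor_ids[i, ]
    if (include_self) nb <- c(i, nb)
    vals[, i] <- rowMeans(b$values[, nb, drop = FALSE])
  }
  structure(list(values = vals, k_used = g$k,
                 gene_ids = b$gene_ids, cell_ids = b$cell_ids),
            class = "recovered_matrix")
}

#' Evaluate recovered expression against normalized truth
#'
#' Pearson correlation per gene (across cells) or per cell (across genes)
#' between the neighborhood detection rates and the true normalized
#' expression, with the median as summary. Constant vectors (in either
#' input) have no defined correlation and are skipped with a warning.
#'
#' @param r a \code{recovered_matrix}.
#' @param truth a \code{normalized_matrix} of the same shape.
#' @param scope \code{"per_gene"} or \code{"per_cell"}.
#' @return List: \code{correlations} (NA where skipped), \code{median}
#'   (over defined values), \code{scope}.
#' @export
evaluate_recovery <- function(r, truth, scope = c("per_gene", "per_cell")) {
  scope <- match.arg(scope)
  if (!identical(dim(r$values), dim(truth$values)))
    stop("recovered and truth matrices must have the same shape")
  margin <- if (scope == "per_gene") 1 else 2
  n_vec <- dim(r$values)[margin]
  cors <- vapply(seq_len(n_vec), function(i) {
    x <- if (margin == 1) r$values[i, ] else r$values[, i]
    y <- if (margin == 1) truth$values[i, ] else truth$values[, i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  n_skip <- sum(is.na(cors))
  if (n_skip == n_vec) stop("no non-constant vectors to correlate")
  if (n_skip > 0) warning(n_skip, " constant vector(s) skipped")
  list(correlations = cors, median = stats::median(cors, na.rm = TRUE),
       scope = scope)
}
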