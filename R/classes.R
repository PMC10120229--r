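#' Construct a count matrix
#'
#' The central input container: a gene-by-cell matrix of non-negative integer
#' UMI/read counts with unique gene and cell identifiers and optional per-cell
#' metadata (sample of origin, condition of the sample, cell type).
#'
#' @param values numeric matrix, genes x cells, non-negative integers.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of \code{values}).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   colnames of \code{values}).
#' @param cell_meta optional data.frame with a \code{cell_id} column and any of
#'   \code{sample_id}, \code{condition}, \code{cell_type}; matched to cells by
#'   \code{cell_id}.
#' @return An object of class \code{count_matrix}: list with elements
#'   \code{values} (integer matrix with dimnames), \code{gene_ids},
#'   \code{cell_ids}, \code{cell_meta}.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values), cell_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("gene_ids/cell_ids lengths must match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (any(!is.finite(values)) || any(values < 0))
    stop("counts must be finite and non-negative")
  if (any(values != round(values)))
    stop("counts must be integral")
  storage.mode(values) <- "double"  # doubles: avoids int overflow on sums
  dimnames(values) <- list(gene_ids, cell_ids)
  meta <- normalize_cell_meta(cell_meta, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = meta),
            class = "count_matrix")
}

normalize_cell_meta <- function(cell_meta, cell_ids) {
  if (is.null(cell_meta)) return(NULL)
  cell_meta <- as.data.frame(cell_meta)
  if (!"cell_id" %in% names(cell_meta))
    stop("cell_meta must have a cell_id column")
  missing <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(missing))
    stop("cell_meta is missing cells: ", paste(head(missing, 5), collapse = ", "))
  unknown <- setdiff(cell_meta$cell_id, cell_ids)
  if (length(unknown))
    stop("cell_meta has unknown cell ids: ", paste(head(unknown, 5), collapse = ", "))
  cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, detection rate %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$values > 0)))
  if (!is.null(x$cell_meta))
    cat("  cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Log CP10K normalization
#'
#' Scales each cell to 10,000 total counts and applies \code{log1p}:
#' entry = ln(1 + 1e4 * count / cell_total). Zeros are preserved exactly, so
#' the detection pattern of the normalized matrix equals that of the counts.
#'
#' @param m a \code{count_matrix}.
#' @return A \code{normalized_matrix} (same structure, real values).
#' @export
normalize_log_cp10k <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- colSums(m$values)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(head(m$cell_ids[totals == 0], 5), collapse = ", "))
  vals <- log1p(sweep(m$values, 2, 1e4 / totals, `*`))
  structure(list(values = vals, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                 cell_meta = m$cell_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (log CP10K)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Binarize a count matrix
#'
#' Zero remains zero and every non-zero value is assigned a one; the result is
#' the detection pattern of the data. Idempotent: binarizing an already binary
#' matrix changes nothing.
#'
#' @param m a \code{count_matrix} or \code{normalized_matrix}.
#' @return A \code{binary_matrix}: list with a 0/1 integer \code{values}
#'   matrix and the same ids/metadata as the input.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, c("count_matrix", "normalized_matrix", "binary_matrix")))
  if (inherits(m, "binary_matrix")) return(m)
  vals <- (m$values > 0) * 1
  dimnames(vals) <- dimnames(m$values)
  structure(list(values = vals, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                 cell_meta = m$cell_meta),
            class = "binary_matrix")
}

#' Construct a binary matrix directly from 0/1 values
#'
#' @inheritParams count_matrix
#' @return A \code{binary_matrix}.
#' @export
binary_matrix <- function(values, gene_ids = rownames(values),
                          cell_ids = colnames(values), cell_meta = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) stop("binary matrix entries must be 0 or 1")
  cm <- count_matrix(values, gene_ids, cell_ids, cell_meta)
  binarize(cm)
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix: %d genes x %d cells, detection rate %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' Detection rates per gene or per cell
#'
#' The detection rate is the fraction of non-zero entries: per gene, the
#' fraction of cells in which the gene is detected; per cell, the fraction of
#' genes detected in that cell.
#'
#' @param b a \code{binary_matrix} (count/normalized matrices are binarized
#'   first).
#' @param axis \code{"gene"} or \code{"cell"}.
#' @return Named numeric vector of fractions in [0, 1].
#' @export
detection_rates <- function(b, axis = c("gene", "cell")) {
  axis <- match.arg(axis)
  b <- binarize(b)
  if (nrow(b$values) == 0 || ncol(b$values) == 0) stop("empty matrix")
  if (axis == "gene") rowMeans(b$values) else colMeans(b$values)
}

#' Shuffle non-zero counts within genes
#'
#' The permutation control: within each gene, the multiset of non-zero counts
#' is permuted uniformly among that gene's detected positions. The detection
#' pattern (and hence the binarized matrix), each gene's count multiset, and
#' per-gene sums are all unchanged.
#'
#' @param m a \code{count_matrix}.
#' @param seed integer seed; the result is reproducible given the seed.
#' @return A \code{count_matrix} with shuffled non-zero values.
#' @export
shuffle_nonzeros <- function(m, seed) {
  stopifnot(inherits(m, "count_matrix"))
  vals <- m$values
  with_seed(seed, {
    for (g in seq_len(nrow(vals))) {
      nz <- which(vals[g, ] > 0)
      if (length(nz) > 1) vals[g, nz] <- vals[g, sample(nz)]
    }
  })
  out <- m
  out$values <- vals
  out
}
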