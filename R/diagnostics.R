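#' Per-cell concordance between binary and normalized expression
#'
#' For each cell, \code{p} is the point-biserial correlation (Pearson
#' correlation across genes) between the cell's normalized values and its 0/1
#' detections. Its predictor \code{q} is the product of the cell's detection
#' rate and the unbiased sample variance of its non-zero normalized values
#' (0 when the cell has exactly one non-zero gene). Cells with a constant
#' normalized vector have no defined correlation and get \code{NA} with a
#' warning.
#'
#' @param norm a \code{normalized_matrix}.
#' @param b the matching \code{binary_matrix} (same genes and cells, same
#'   order).
#' @return A data.frame of class \code{cell_diagnostics} with columns
#'   \code{cell_id}, \code{p}, \code{q}, \code{detection_rate},
#'   \code{var_nonzero}.
#' @export
cell_concordance <- function(norm, b) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(b, "binary_matrix"))
  if (!identical(dim(norm$values), dim(b$values)))
    stop("normalized and binary matrices must have the same shape")
  if (!identical(norm$cell_ids, b$cell_ids) ||
      !identical(norm$gene_ids, b$gene_ids))
    stop("normalized and binary matrices must have identical gene/cell ids")
  nc <- ncol(norm$values)
  p <- q <- dr <- vnz <- numeric(nc)
  n_const <- 0
  for (c in seq_len(nc)) {
    x <- norm$values[, c]
    y <- b$values[, c]
    dr[c] <- mean(y)
    nzv <- x[y == 1]
    vnz[c] <- if (length(nzv) >= 2) stats::var(nzv) else 0
    q[c] <- dr[c] * vnz[c]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      p[c] <- NA_real_
      n_const <- n_const + 1
    } else {
      p[c] <- stats::cor(x, y)
    }
  }
  if (n_const > 0)
    warning(n_const, " cell(s) with constant vectors: p undefined (NA)")
  structure(data.frame(cell_id = norm$cell_ids, p = p, q = q,
                       detection_rate = dr, var_nonzero = vnz,
                       stringsAsFactors = FALSE),
            class = c("cell_diagnostics", "data.frame"))
}

#' Dataset-level alpha statistic
#'
#' The Pearson correlation between the per-cell concordance \code{p} and its
#' predictor \code{q} across all cells of a dataset. Cells whose \code{p} is
#' undefined are dropped pairwise.
#'
#' @param d a \code{cell_diagnostics} data.frame from
#'   \code{\link{cell_concordance}}.
#' @return A single correlation in [-1, 1].
#' @export
alpha_statistic <- function(d) {
  stopifnot(inherits(d, "cell_diagnostics") ||
            all(c("p", "q") %in% names(d)))
  ok <- stats::complete.cases(d$p, d$q)
  if (sum(ok) < 3) stop("need at least 3 cells with defined p")
  stats::cor(d$p[ok], d$q[ok])
}
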