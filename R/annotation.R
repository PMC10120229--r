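#' Read marker sets from TSV or JSON
#'
#' TSV needs two columns, \code{cell_type} and \code{gene_id} (header
#' optional if in that order); JSON is a mapping from cell type to an array
#' of gene ids.
#'
#' @param path marker file.
#' @return Named list: cell type -> character vector of marker gene ids.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite required to read JSON marker files")
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(m, as.character))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (identical(tolower(unlist(tab[1, ])), c("cell_type", "gene_id")))
    tab <- tab[-1, , drop = FALSE]
  split(as.character(tab[[2]]), tab[[1]])
}

#' Annotate cells from marker detection alone
#'
#' Each cell is scored against each cell type as the fraction of that type's
#' marker genes the cell detects; the label is the unique argmax with a
#' positive score, and ties or all-zero scores give \code{"unassigned"}.
#' Annotation depends only on the detection pattern, so it is invariant to
#' any reshuffling of the non-zero counts.
#'
#' @param b a \code{binary_matrix}.
#' @param markers named list mapping cell type to marker gene ids; markers
#'   absent from the matrix are dropped with a warning, and a type with no
#'   usable markers is an error.
#' @return List of class \code{annotation_result}: \code{labels} (per cell),
#'   \code{scores} (cells x types in [0, 1]).
#' @export
annotate_by_markers <- function(b, markers) {
  b <- binarize(b)
  stopifnot(is.list(markers), length(markers) >= 1)
  usable <- lapply(markers, intersect, b$gene_ids)
  dropped <- sum(lengths(markers)) - sum(lengths(usable))
  if (dropped > 0)
    warning(dropped, " marker gene(s) not present in the matrix; dropped")
  empty <- names(usable)[lengths(usable) == 0]
  if (length(empty))
    stop("cell types with no usable markers: ", paste(empty, collapse = ", "))
  types <- names(usable)
  scores <- vapply(types, function(ty) {
    colMeans(b$values[usable[[ty]], , drop = FALSE])
  }, numeric(ncol(b$values)))
  scores <- matrix(scores, ncol = length(types),
                   dimnames = list(b$cell_ids, types))
  labels <- apply(scores, 1, function(s) {
    top <- max(s)
    if (top == 0 || sum(s == top) > 1) "unassigned" else types[which.max(s)]
  })
  structure(list(labels = unname(labels), scores = scores,
                 cell_ids = b$cell_ids),
            class = "annotation_result")
}

#' Per-type F1 scores against reference labels
#'
#' Precision, recall, and F1 per cell type, plus the unweighted median F1
#' over the types present in the reference. \code{"unassigned"} predictions
#' count as wrong for their true class and are never a true positive.
#'
#' @param pred_labels predicted labels (may include \code{"unassigned"}).
#' @param true_labels reference labels of the same length.
#' @return List with \code{per_type} data.frame (type, precision, recall,
#'   f1) and \code{median_f1}.
#' @export
f1_scores <- function(pred_labels, true_labels) {
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  if (length(pred_labels) == 0 || length(pred_labels) != length(true_labels))
    stop("label vectors must be non-empty and of equal length")
  types <- sort(unique(true_labels))
  rows <- lapply(types, function(ty) {
    tp <- sum(pred_labels == ty & true_labels == ty)
    fp <- sum(pred_labels == ty & true_labels != ty)
    fn <- sum(pred_labels != ty & true_labels == ty)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(type = ty, precision = prec, recall = rec, f1 = f1)
  })
  per_type <- do.call(rbind, rows)
  list(per_type = per_type, median_f1 = stats::median(per_type$f1))
}
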