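#' Read a count matrix from MTX or dense TSV
#'
#' MTX input is Matrix Market coordinate format (1-based triplets) with
#' optional \code{genes.tsv} / \code{barcodes.tsv} sidecars next to the file;
#' dense TSV has one gene per row (first column gene id) and one cell per
#' column. Duplicate MTX coordinates are an error rather than being summed:
#' silent summation hides corrupt input.
#'
#' @param path path to the .mtx file or the dense TSV.
#' @param format \code{"mtx"} or \code{"dense_tsv"}.
#' @param metadata_path optional TSV with columns \code{cell_id},
#'   \code{sample_id}, \code{condition}, \code{cell_type} (any subset beyond
#'   cell_id), joined to cells by id.
#' @return A \code{count_matrix}.
#' @export
read_counts <- function(path, format = c("mtx", "dense_tsv"),
                        metadata_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    # readMM sums duplicate coordinates; detect them by re-reading triplets
    body <- utils::read.table(path, comment.char = "%", header = FALSE)
    trip <- body[-1, , drop = FALSE]  # first non-comment row is the dims line
    if (nrow(trip) > 0 && anyDuplicated(trip[, 1:2]))
      stop("duplicate coordinates in MTX file: ", path)
    vals <- as.matrix(m)
    gene_ids <- cell_ids <- NULL
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv"); bf <- file.path(dir, "barcodes.tsv")
    if (file.exists(gf))
      gene_ids <- utils::read.table(gf, header = FALSE,
                                    stringsAsFactors = FALSE)[, 1]
    if (file.exists(bf))
      cell_ids <- utils::read.table(bf, header = FALSE,
                                    stringsAsFactors = FALSE)[, 1]
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(vals)))
    if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(vals)))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(tab)
    gene_ids <- rownames(tab)
    cell_ids <- colnames(tab)
  }
  meta <- NULL
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
    meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  count_matrix(vals, gene_ids, cell_ids, cell_meta = meta)
}

#' Write a count matrix as MTX plus sidecars
#'
#' Writes \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv} and, when
#' metadata is present, \code{metadata.tsv} into \code{dir}.
#'
#' @param m a \code{count_matrix}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_counts_mtx <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE), "generalMatrix"), mtx)
  utils::write.table(m$gene_ids, file.path(dir, "genes.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(m$cell_ids, file.path(dir, "barcodes.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- c(mtx, file.path(dir, c("genes.tsv", "barcodes.tsv")))
  if (!is.null(m$cell_meta)) {
    mp <- file.path(dir, "metadata.tsv")
    utils::write.table(m$cell_meta, mp, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    paths <- c(paths, mp)
  }
  invisible(paths)
}

# --- BBM: bit-packed binary matrix format -----------------------------------
# 24-byte header: magic "BBM1", 4 reserved zero bytes, n_genes and n_cells as
# little-endian uint64. Payload is gene-major; each gene row is padded to a
# whole byte; bits are packed LSB-first within each byte.

#' Write a binary matrix in BBM format
#'
#' @param b a \code{binary_matrix}.
#' @param path output file; a sidecar \code{<path>.ids.tsv} with gene and cell
#'   ids is written alongside.
#' @return Invisibly, \code{path}.
#' @export
write_bbm <- function(b, path) {
  stopifnot(inherits(b, "binary_matrix"))
  ng <- nrow(b$values); nc <- ncol(b$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BBM1"), con)
  writeBin(as.raw(rep(0, 4)), con)
  write_uint64_le(con, ng)
  write_uint64_le(con, nc)
  pad <- (-nc) %% 8
  for (g in seq_len(ng)) {
    bits <- c(b$values[g, ], rep(0, pad))
    writeBin(packBits(as.raw(bits), type = "raw"), con)
  }
  ids <- data.frame(kind = c(rep("gene", ng), rep("cell", nc)),
                    id = c(b$gene_ids, b$cell_ids))
  utils::write.table(ids, paste0(path, ".ids.tsv"), quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

write_uint64_le <- function(con, n) {
  # n below 2^31 in practice; write as two little-endian uint32 words
  writeBin(as.integer(n %% 2^32), con, size = 4, endian = "little")
  writeBin(as.integer(n %/% 2^32), con, size = 4, endian = "little")
}

read_uint64_le <- function(con) {
  lo <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  hi <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(lo) < 1 || length(hi) < 1) stop("truncated BBM header")
  lo + hi * 2^32
}

#' Read a binary matrix in BBM format
#'
#' @param path BBM file written by \code{\link{write_bbm}}; the
#'   \code{<path>.ids.tsv} sidecar is used for ids when present.
#' @return A \code{binary_matrix}.
#' @export
read_bbm <- function(path) {
  if (!file.exists(path)) stop("BBM file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || !identical(rawToChar(magic), "BBM1"))
    stop("bad BBM magic in ", path)
  readBin(con, "raw", n = 4)  # reserved
  ng <- read_uint64_le(con)
  nc <- read_uint64_le(con)
  bpr <- ceiling(nc / 8)
  payload <- readBin(con, "raw", n = ng * bpr)
  if (length(payload) < ng * bpr)
    stop("truncated BBM payload: expected ", ng * bpr, " bytes, got ",
         length(payload))
  vals <- matrix(0, nrow = ng, ncol = nc)
  for (g in seq_len(ng)) {
    row_bytes <- payload[((g - 1) * bpr + 1):(g * bpr)]
    bits <- as.integer(rawToBits(row_bytes))
    vals[g, ] <- bits[seq_len(nc)]
  }
  gene_ids <- cell_ids <- NULL
  sidecar <- paste0(path, ".ids.tsv")
  if (file.exists(sidecar)) {
    ids <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    gene_ids <- ids$id[ids$kind == "gene"]
    cell_ids <- ids$id[ids$kind == "cell"]
    if (length(gene_ids) != ng || length(cell_ids) != nc)
      stop("BBM sidecar dimensions do not match header in ", path)
  }
  binary_matrix(vals, gene_ids = gene_ids, cell_ids = cell_ids)
}

#' Storage accounting for the three representations
#'
#' Byte counts for storing a matrix dense as float64 (G*C*8 bytes), as a
#' sparse triplet (12 bytes per non-zero: two int32 indices plus a float32
#' value), and bit-packed in the BBM layout (one bit per entry, gene rows
#' padded to whole bytes, plus the 24-byte header).
#'
#' @param m a \code{count_matrix} (or binary/normalized matrix).
#' @return A list of class \code{storage_report}: byte counts, fold
#'   reductions vs dense and vs sparse, and the overall detection rate.
#' @export
storage_report <- function(m) {
  vals <- m$values
  G <- nrow(vals); C <- ncol(vals)
  nnz <- sum(vals != 0)
  dense <- G * C * 8
  sparse <- nnz * 12
  bitpacked <- G * ceiling(C / 8) + 24
  structure(list(bytes_dense_float64 = dense,
                 bytes_sparse_triplet = sparse,
                 bytes_bitpacked = bitpacked,
                 fold_vs_dense = dense / bitpacked,
                 fold_vs_sparse = sparse / bitpacked,
                 detection_rate = nnz / (G * C)),
            class = "storage_report")
}

#' @export
print.storage_report <- function(x, ...) {
  cat(sprintf(paste0("storage: dense %d B, sparse %d B, bitpacked %d B ",
                     "(%.1f-fold vs dense, %.1f-fold vs sparse), detection %.3f\n"),
              x$bytes_dense_float64, x$bytes_sparse_triplet, x$bytes_bitpacked,
              x$fold_vs_dense, x$fold_vs_sparse, x$detection_rate))
  invisible(x)
}
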