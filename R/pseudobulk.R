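#' Aggregate cells to sample-level pseudobulk
#'
#' Collapses cells into one profile per sample, either as the mean of the
#' supplied values per gene (\code{mode = "mean"}, intended for log CP10K
#' values) or as the detection rate, i.e. the fraction of non-zero values
#' across the sample's cells (\code{mode = "detection_rate"}). Detection-rate
#' aggregation of a matrix is exactly mean aggregation of its binarized
#' version.
#'
#' @param m a \code{normalized_matrix}, \code{binary_matrix} or
#'   \code{count_matrix}.
#' @param sample_of_cell sample id per cell (defaults to the
#'   \code{sample_id} metadata column).
#' @param mode \code{"mean"} or \code{"detection_rate"}.
#' @param condition_of_sample optional named vector (sample -> condition);
#'   taken from metadata when present.
#' @return A \code{pseudobulk_table}: \code{values} (samples x genes),
#'   \code{mode}, \code{sample_ids}, \code{condition}, \code{n_cells}.
#' @export
aggregate_pseudobulk <- function(m, sample_of_cell = NULL,
                                 mode = c("mean", "detection_rate"),
                                 condition_of_sample = NULL) {
  mode <- match.arg(mode)
  if (is.null(sample_of_cell)) {
    if (is.null(m$cell_meta) || is.null(m$cell_meta$sample_id))
      stop("sample_of_cell not given and no sample_id metadata present")
    sample_of_cell <- m$cell_meta$sample_id
  }
  sample_of_cell <- as.character(sample_of_cell)
  if (length(sample_of_cell) != ncol(m$values))
    stop("sample_of_cell must have one entry per cell")
  vals <- if (mode == "detection_rate") (m$values > 0) * 1 else m$values
  samples <- unique(sample_of_cell)
  pb <- t(vapply(samples, function(s) {
    rowMeans(vals[, sample_of_cell == s, drop = FALSE])
  }, numeric(nrow(vals))))
  rownames(pb) <- samples
  colnames(pb) <- m$gene_ids
  cond <- NULL
  if (!is.null(condition_of_sample)) {
    miss <- setdiff(samples, names(condition_of_sample))
    if (length(miss)) stop("no condition for sample(s): ",
                           paste(miss, collapse = ", "))
    cond <- unname(condition_of_sample[samples])
  } else if (!is.null(m$cell_meta) && !is.null(m$cell_meta$condition)) {
    cond <- vapply(samples, function(s) {
      u <- unique(m$cell_meta$condition[sample_of_cell == s])
      if (length(u) != 1) stop("sample ", s, " maps to multiple conditions")
      as.character(u)
    }, character(1))
    cond <- unname(cond)
  }
  structure(list(values = pb, mode = mode, sample_ids = samples,
                 condition = cond,
                 n_cells = as.vector(table(sample_of_cell)[samples])),
            class = "pseudobulk_table")
}

#' @export
print.pseudobulk_table <- function(x, ...) {
  cat(sprintf("pseudobulk_table (%s): %d samples x %d genes\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement, capped at 1.
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group pseudobulk differential expression
#'
#' Two routes over a two-condition pseudobulk table:
#' \describe{
#'   \item{\code{detection_t}}{per-gene two-sided t-test on detection rates
#'     between conditions; Welch by default, pooled when
#'     \code{equal_var = TRUE} or when one group is constant (with a
#'     warning).}
#'   \item{\code{moderated_trend}}{per-gene linear model on mean values with
#'     empirical-Bayes variance shrinkage toward an intensity-dependent
#'     prior: the prior variance s0^2 comes from a quadratic fit of
#'     log(s^2) on mean abundance (bias-corrected for the chi-square
#'     expectation of log s^2) and the prior df d0 from moment matching of
#'     the log-variance residuals against trigamma(d/2); posterior variance
#'     (d0*s0^2 + d*s^2) / (d0 + d), moderated t with d0 + d df.}
#' }
#' Genes with zero variance in both groups and zero effect get p = 1.
#' P-values are BH-adjusted; \code{call} flags adjusted p <= alpha.
#'
#' @param pb a \code{pseudobulk_table} with exactly two conditions and at
#'   least two samples in each.
#' @param route \code{"detection_t"} or \code{"moderated_trend"}.
#' @param alpha FDR level for calls (default 0.05).
#' @param equal_var use the pooled-variance t-test in the
#'   \code{detection_t} route.
#' @param d0_override force the moderated route's prior df (0 recovers the
#'   ordinary pooled t-test exactly); mainly for validation.
#' @return A data.frame of class \code{de_result}: gene, effect (difference
#'   of group means, condition 2 minus condition 1 in sorted label order),
#'   stat, df, p, padj, call.
#' @export
de_test <- function(pb, route = c("detection_t", "moderated_trend"),
                    alpha = 0.05, equal_var = FALSE, d0_override = NULL) {
  route <- match.arg(route)
  stopifnot(inherits(pb, "pseudobulk_table"))
  if (is.null(pb$condition)) stop("pseudobulk table has no condition labels")
  conds <- sort(unique(pb$condition))
  if (length(conds) != 2) stop("need exactly two conditions")
  i1 <- pb$condition == conds[1]
  i2 <- pb$condition == conds[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per condition")
  X <- pb$values
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(X[i2, , drop = FALSE], 2, stats::var)
  effect <- m2 - m1
  G <- ncol(X)
  if (route == "detection_t") {
    one_const <- xor(v1 == 0, v2 == 0)
    if (!equal_var && any(one_const))
      warning(sum(one_const),
              " gene(s) constant in one group: pooled variance used there")
    use_pooled <- equal_var | one_const
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se_w <- sqrt(v1 / n1 + v2 / n2)
    se_p <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df_w <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df_p <- rep(n1 + n2 - 2, G)
    se <- ifelse(use_pooled, se_p, se_w)
    df <- ifelse(use_pooled, df_p, df_w)
    stat <- effect / se
    p <- 2 * stats::pt(-abs(stat), df)
    degen <- v1 == 0 & v2 == 0 & effect == 0
    stat[degen] <- 0; p[degen] <- 1; df[degen] <- df_p[degen]
    # both groups constant but different: no within-group replication, so
    # the t framework supports no inference; conservative p = 1
    sep <- v1 == 0 & v2 == 0 & effect != 0
    stat[sep] <- sign(effect[sep]) * Inf; p[sep] <- 1; df[sep] <- df_p[sep]
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d  # pooled residual variance
    abund <- (n1 * m1 + n2 * m2) / (n1 + n2)
    sq <- squeeze_var_trend(s2, d, abund, d0_override)
    se <- sqrt(sq$var_post * (1 / n1 + 1 / n2))
    df <- rep(d + sq$d0, G)
    df[!is.finite(df)] <- 1e6  # d0 = Inf: effectively normal reference
    stat <- effect / se
    p <- 2 * stats::pt(-abs(stat), df)
    degen <- s2 == 0 & effect == 0
    stat[degen] <- 0; p[degen] <- 1
    sep <- s2 == 0 & effect != 0 & !is.finite(stat)
    p[sep] <- 0
  }
  padj <- bh_adjust(p)
  structure(data.frame(gene = colnames(X), effect = effect, stat = stat,
                       df = df, p = p, padj = padj, call = padj <= alpha,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

# Empirical-Bayes variance shrinkage with a quadratic intensity trend.
# z = log(s2) has E[z] = log(sigma2) + digamma(d/2) - log(d/2) under the
# scaled chi-square model; the trend is fit on z and bias-corrected to give
# s0^2(abundance). d0 solves trigamma(d0/2) = var(resid) - trigamma(d/2) by
# moment matching (Inf when the residual variance is already at or below the
# chi-square floor).
squeeze_var_trend <- function(s2, d, abund, d0_override = NULL) {
  pos <- s2 > 0
  if (sum(pos) < 4) {
    s0 <- rep(mean(s2), length(s2))
    d0 <- 0
  } else {
    z <- log(s2[pos])
    a <- abund[pos]
    fit <- stats::lm(z ~ a + I(a^2))
    pred <- stats::predict(fit, newdata = data.frame(a = abund))
    s0 <- exp(pred - digamma(d / 2) + log(d / 2))
    resid_var <- stats::var(stats::residuals(fit))
    excess <- resid_var - trigamma(d / 2)
    d0 <- if (excess <= 0) Inf else 2 * trigamma_inverse(excess)
  }
  if (!is.null(d0_override)) d0 <- d0_override
  var_post <- if (is.infinite(d0)) s0
              else if (d0 == 0) s2
              else (d0 * s0 + d * s2) / (d0 + d)
  list(var_post = var_post, var_prior = s0, d0 = d0)
}

# Solve trigamma(y) = x by Newton iteration on the monotone decreasing map.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Confusion summary of DE calls against simulation truth
#'
#' Counts true/false positives/negatives of the \code{call} column against
#' known DE labels, with precision, recall, F1, and false negatives binned
#' by overall gene detection rate (to locate where the detection-rate route
#' loses signal).
#'
#' @param r a \code{de_result}.
#' @param truth a \code{sim_truth} (or any list with \code{gene} and
#'   \code{is_de}).
#' @param gene_detection named vector of overall per-gene detection rates
#'   (optional; needed for the FN-by-bin breakdown).
#' @param bins detection-rate bin edges (default 0, 0.1, ..., 1).
#' @return List of class \code{confusion_summary}: TP, FP, FN, TN,
#'   precision, recall, f1, fn_by_detection_bin.
#' @export
evaluate_de <- function(r, truth, gene_detection = NULL,
                        bins = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(r, "de_result"))
  if (!setequal(r$gene, truth$gene)) stop("gene sets of result and truth differ")
  is_de <- truth$is_de[match(r$gene, truth$gene)]
  tp <- sum(r$call & is_de); fp <- sum(r$call & !is_de)
  fn <- sum(!r$call & is_de); tn <- sum(!r$call & !is_de)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  fn_bins <- NULL
  if (!is.null(gene_detection)) {
    gd <- gene_detection[match(r$gene, names(gene_detection))]
    if (any(is.na(gd))) stop("gene_detection missing genes")
    cut_ <- cut(gd, breaks = bins, include.lowest = TRUE)
    fn_bins <- table(cut_[!r$call & is_de])
  }
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn, precision = prec,
                 recall = rec, f1 = f1, fn_by_detection_bin = fn_bins),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d FN=%d TN=%d  P=%.3f R=%.3f F1=%.3f\n",
              x$TP, x$FP, x$FN, x$TN, x$precision, x$recall, x$f1))
  invisible(x)
}
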