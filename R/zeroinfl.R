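#' Fit Poisson, NB, ZIP and ZINB to a gene's counts
#'
#' Maximum-likelihood fits of the four candidate count models to one gene's
#' counts across cells, with model selection by BIC
#' (-2 loglik + k log n; k = 1, 2, 2, 3):
#' \itemize{
#'   \item Poisson: lambda = sample mean (closed form).
#'   \item NB (mean/size parameterization, variance mu + mu^2/theta): mu at
#'     the sample mean (profile MLE), theta by 1-D optimization of the
#'     profile log-likelihood on the log scale.
#'   \item ZIP / ZINB: EM over the latent structural-zero indicator.
#'     Initialization: pi0 = max(0, (zero fraction - model zero probability
#'     at the non-inflated fit) / (1 - that probability)); count parameters
#'     start at the non-inflated fit. Convergence when the log-likelihood
#'     gain drops below 1e-8, at most 500 iterations; non-convergence falls
#'     back to the non-inflated counterpart with a warning.
#' }
#' A gene is called zero-inflated when the BIC-selected model is ZIP or ZINB.
#'
#' @param counts non-negative integer vector (one gene across cells); all
#'   zero is an error, fewer than 20 observations draws a warning.
#' @return List of class \code{model_fit}: per-model \code{loglik},
#'   \code{params}, \code{bic}, plus \code{selected} and
#'   \code{zero_inflated}.
#' @export
fit_count_models <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (all(counts == 0)) stop("all-zero gene: no model is identifiable")
  n <- length(counts)
  if (n < 20) warning("fewer than 20 observations; fits may be unstable")

  lam <- mean(counts)
  ll_pois <- sum(stats::dpois(counts, lam, log = TRUE))

  nb <- fit_nb(counts)
  zip <- fit_zi_em(counts, family = "poisson",
                   init = list(lambda = lam), ll_base = ll_pois)
  zinb <- fit_zi_em(counts, family = "nbinom",
                    init = list(mu = nb$mu, theta = nb$theta),
                    ll_base = nb$loglik)

  loglik <- c(poisson = ll_pois, nbinom = nb$loglik,
              zip = zip$loglik, zinb = zinb$loglik)
  kpar <- c(poisson = 1, nbinom = 2, zip = 2, zinb = 3)
  bic <- -2 * loglik + kpar * log(n)
  selected <- names(bic)[which.min(bic)]
  structure(list(
    loglik = loglik, bic = bic,
    params = list(poisson = list(lambda = lam),
                  nbinom = list(mu = nb$mu, theta = nb$theta),
                  zip = list(pi = zip$pi, lambda = zip$lambda),
                  zinb = list(pi = zinb$pi, mu = zinb$mu, theta = zinb$theta)),
    selected = selected,
    zero_inflated = selected %in% c("zip", "zinb"),
    n = n), class = "model_fit")
}

# NB profile MLE: mu-hat is the sample mean for any theta; optimize theta.
fit_nb <- function(counts, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(counts))
  mu <- sum(weights * counts) / sum(weights)
  if (mu == 0) return(list(mu = 0, theta = Inf, loglik = 0))
  nll <- function(lt) {
    -sum(weights * stats::dnbinom(counts, size = exp(lt), mu = mu, log = TRUE))
  }
  opt <- stats::optimize(nll, interval = c(log(1e-3), log(1e8)), tol = 1e-9)
  theta <- exp(opt$minimum)
  # near the upper bound the NB has converged to its Poisson limit
  list(mu = mu, theta = theta, loglik = -opt$objective)
}

# EM for zero-inflated Poisson/NB over the structural-zero indicator.
fit_zi_em <- function(counts, family = c("poisson", "nbinom"), init,
                      ll_base, max_iter = 500, tol = 1e-8) {
  family <- match.arg(family)
  n <- length(counts)
  zero <- counts == 0
  dcount <- function(x, par, log = FALSE) {
    if (family == "poisson") stats::dpois(x, par$lambda, log = log)
    else stats::dnbinom(x, size = par$theta, mu = par$mu, log = log)
  }
  par <- init
  p0 <- dcount(0, par)
  pi <- max(0, (mean(zero) - p0) / (1 - p0))
  if (!is.finite(pi)) pi <- 0
  obs_ll <- function(pi, par) {
    sum(log(pi * zero + (1 - pi) * dcount(counts, par)))
  }
  ll <- obs_ll(pi, par)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: posterior probability that a zero is structural
    p0 <- dcount(0, par)
    w <- ifelse(zero, pi / (pi + (1 - pi) * p0), 0)
    # M-step
    pi_new <- mean(w)
    wt <- 1 - w
    if (sum(wt) == 0) break
    if (family == "poisson") {
      par_new <- list(lambda = sum(wt * counts) / sum(wt))
    } else {
      nb <- fit_nb(counts, weights = wt)
      par_new <- list(mu = nb$mu, theta = nb$theta)
    }
    ll_new <- obs_ll(pi_new, par_new)
    if (ll_new >= ll - 1e-10) { pi <- pi_new; par <- par_new }
    # EM is monotone up to inner-optimizer noise: a gain below tol (or any
    # numerical decrease) means we are at the optimum
    if (ll_new - ll < tol) { ll <- max(ll, ll_new); converged <- TRUE; break }
    ll <- ll_new
  }
  if (!converged && it == max_iter)
    warning("zero-inflated ", family, " EM did not converge; ",
            "falling back to the non-inflated fit")
  if ((!converged && it == max_iter) || ll < ll_base - 1e-8) {
    pi <- 0; par <- init; ll <- ll_base
  }
  c(list(pi = pi, loglik = ll), par)
}

#' Rank genes by a two-proportion detection-rate statistic
#'
#' Per gene, the two-proportion z statistic on detection rates between two
#' cell groups, z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2)) with p the
#' pooled rate. \code{mode = "de"} ranks by descending |z| (most
#' differentially detected first); \code{mode = "stable"} ranks by ascending
#' |z| among genes detected at rate >= 0.1 in both groups, so that
#' never-expressed genes do not masquerade as stable.
#'
#' @param b a \code{binary_matrix}.
#' @param group_of_cell two-level grouping, one entry per cell.
#' @param mode \code{"de"} or \code{"stable"}.
#' @param top_n number of genes to return (default 100).
#' @return Data.frame: gene, z, detection rates per group, rank order as
#'   returned. Ties are broken by gene index.
#' @export
rank_genes_binary <- function(b, group_of_cell, mode = c("de", "stable"),
                              top_n = 100) {
  mode <- match.arg(mode)
  b <- binarize(b)
  group_of_cell <- as.character(group_of_cell)
  stopifnot(length(group_of_cell) == ncol(b$values))
  groups <- sort(unique(group_of_cell))
  if (length(groups) != 2) stop("need exactly two groups")
  i1 <- group_of_cell == groups[1]; i2 <- group_of_cell == groups[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (min(n1, n2) < 20) warning("a group has fewer than 20 cells")
  p1 <- rowMeans(b$values[, i1, drop = FALSE])
  p2 <- rowMeans(b$values[, i2, drop = FALSE])
  pp <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (p1 - p2) / se)
  df <- data.frame(gene = b$gene_ids, z = z, rate1 = p1, rate2 = p2,
                   idx = seq_along(z), stringsAsFactors = FALSE)
  if (mode == "stable") {
    df <- df[p1 >= 0.1 & p2 >= 0.1, , drop = FALSE]
    df <- df[order(abs(df$z), df$idx), , drop = FALSE]
  } else {
    df <- df[order(-abs(df$z), df$idx), , drop = FALSE]
  }
  df$idx <- NULL
  utils::head(df, top_n)
}

#' Fisher exact test with conditional-MLE odds ratio
#'
#' Exact inference for a 2x2 table: two-sided p-value by the
#' probability-ordering definition (sum of hypergeometric probabilities of
#' all tables with the same margins whose probability does not exceed the
#' observed one, with a relative guard of 1e-7), odds ratio as the
#' conditional MLE under the noncentral hypergeometric likelihood (infinite
#' at boundary tables), and a 95\% CI from inverting the one-sided
#' conditional tests at 0.025 per tail. These are the conventions of
#' \code{stats::fisher.test}, to which this delegates.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts with positive margins.
#' @return List of class \code{fisher_result}: \code{table},
#'   \code{p_two_sided}, \code{log_or_cmle}, \code{ci95_log}.
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.vector(table) && length(table) == 4)
    table <- matrix(table, 2, 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero margin")
  ft <- stats::fisher.test(table, conf.level = 0.95)
  structure(list(table = table,
                 p_two_sided = ft$p.value,
                 log_or_cmle = log(unname(ft$estimate)),
                 ci95_log = log(as.numeric(ft$conf.int))),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("2x2 table:\n"); print(x$table)
  cat(sprintf("p = %.3g, logOR (CMLE) = %.3g, 95%% CI (%.3g, %.3g)\n",
              x$p_two_sided, x$log_or_cmle, x$ci95_log[1], x$ci95_log[2]))
  invisible(x)
}

#' Enrichment of zero-inflated model fits in DE vs stable genes
#'
#' Builds the 2x2 table (rows: differentially detected vs stable gene lists;
#' columns: zero-inflated vs not, by BIC-selected model) and runs
#' \code{\link{fisher_exact_2x2}}. A positive log odds ratio means
#' zero-inflated fits are enriched among the differentially detected genes
#' — the signature of subpopulation-restricted (marker-like) expression.
#'
#' @param fits named list of \code{model_fit} objects (names are gene ids),
#'   or a named logical vector of zero-inflated calls.
#' @param de_genes,stable_genes disjoint character vectors of gene ids, both
#'   subsets of the fitted genes.
#' @return A \code{fisher_result} (its \code{table} element is the 2x2
#'   table, rows DE/stable, columns zero-inflated/not).
#' @export
zero_inflation_enrichment <- function(fits, de_genes, stable_genes) {
  if (is.list(fits)) {
    zi <- vapply(fits, function(f) f$zero_inflated, logical(1))
  } else zi <- fits
  if (is.null(names(zi))) stop("fits must be named by gene id")
  if (length(intersect(de_genes, stable_genes)))
    stop("de_genes and stable_genes overlap")
  missing <- setdiff(c(de_genes, stable_genes), names(zi))
  if (length(missing))
    stop("genes without fits: ", paste(utils::head(missing, 5), collapse = ", "))
  tab <- rbind(de = c(sum(zi[de_genes]), sum(!zi[de_genes])),
               stable = c(sum(zi[stable_genes]), sum(!zi[stable_genes])))
  colnames(tab) <- c("zero_inflated", "not_zero_inflated")
  fisher_exact_2x2(tab)
}
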