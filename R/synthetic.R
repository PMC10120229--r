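#' Simulation configuration for multi-sample two-condition data
#'
#' Hierarchical negative-binomial generator in the style of multi-sample
#' single-cell simulators: per-gene baseline means are log-normal, per-gene
#' dispersions uniform, every sample gets its own log-normal gene-level
#' factor (biological replicate variability), and a known fraction of genes
#' is differentially expressed between the two conditions with a fixed
#' |log2 fold change| and random sign.
#'
#' Defaults emulate a sparse droplet-style dataset: 1000 genes, 3 samples
#' per condition, 100 cells per sample, 10\% DE genes at |log2 FC| = 1,
#' baseline means LogNormal(meanlog = -1, sdlog = 1.5) (median ~0.37 counts
#' per cell, a long right tail of high expressors), dispersions
#' theta ~ U(0.5, 5), and sample factor sd 0.15 on the log scale.
#'
#' @param n_genes,samples_per_group,cells_per_sample problem size.
#' @param p_de fraction of DE genes.
#' @param lfc magnitude of the log2 fold change of DE genes.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of gene
#'   baseline means.
#' @param theta_range range of the NB size parameter (variance
#'   mu + mu^2/theta).
#' @param sample_effect_sd sd (log scale) of per-sample per-gene factors.
#' @param seed integer seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 1000, samples_per_group = 3,
                       cells_per_sample = 100, p_de = 0.1, lfc = 1,
                       baseline_meanlog = -1, baseline_sdlog = 1.5,
                       theta_range = c(0.5, 5), sample_effect_sd = 0.15,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, samples_per_group = samples_per_group,
              cells_per_sample = cells_per_sample, p_de = p_de, lfc = lfc,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, theta_range = theta_range,
              sample_effect_sd = sample_effect_sd, seed = seed)
  stopifnot(n_genes >= 1, samples_per_group >= 1, cells_per_sample >= 1,
            p_de >= 0, p_de <= 1, lfc >= 0, diff(theta_range) >= 0,
            theta_range[1] > 0, sample_effect_sd >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-sample two-condition count matrix with DE truth
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{counts} (a \code{count_matrix} whose metadata
#'   carries \code{sample_id} and \code{condition}) and \code{truth} (a
#'   \code{sim_truth} data.frame: gene, is_de, lfc — signed log2 fold
#'   change, 0 for nulls).
#' @export
simulate_multisample <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    G <- cf$n_genes
    S <- cf$samples_per_group * 2
    C <- cf$cells_per_sample
    mu <- exp(stats::rnorm(G, cf$baseline_meanlog, cf$baseline_sdlog))
    theta <- stats::runif(G, cf$theta_range[1], cf$theta_range[2])
    is_de <- stats::runif(G) < cf$p_de
    sgn <- sample(c(-1, 1), G, replace = TRUE)
    lfc <- ifelse(is_de, sgn * cf$lfc, 0)
    sample_ids <- paste0("s", seq_len(S))
    condition <- rep(c("A", "B"), each = cf$samples_per_group)
    vals <- matrix(0, G, S * C)
    sample_of_cell <- rep(sample_ids, each = C)
    for (s in seq_len(S)) {
      f <- exp(stats::rnorm(G, 0, cf$sample_effect_sd))
      m_s <- mu * f
      if (condition[s] == "B") m_s <- m_s * 2^lfc
      cols <- ((s - 1) * C + 1):(s * C)
      vals[, cols] <- stats::rnbinom(G * C, size = theta,
                                     mu = rep(m_s, times = C))
    }
    gene_ids <- paste0("g", seq_len(G))
    cell_ids <- paste0("cell", seq_len(S * C))
    meta <- data.frame(cell_id = cell_ids, sample_id = sample_of_cell,
                       condition = rep(condition, each = C),
                       stringsAsFactors = FALSE)
    counts <- count_matrix(vals, gene_ids, cell_ids, cell_meta = meta)
    truth <- structure(data.frame(gene = gene_ids, is_de = is_de, lfc = lfc,
                                  stringsAsFactors = FALSE),
                       class = c("sim_truth", "data.frame"))
    list(counts = counts, truth = truth, config = cf)
  })
}

#' Simulate a multi-cell-type population with markers and housekeeping genes
#'
#' Each cell type carries its own marker genes, drawn NB with a high mean in
#' that type (target detection near \code{detection_high}) and a near-zero
#' mean elsewhere (target detection near \code{detection_low});
#' housekeeping genes have one shared NB distribution in every type;
#' background genes are lowly and uniformly expressed. This is the
#' marker-vs-housekeeping structure under which subpopulation-restricted
#' expression produces zero inflation in pooled counts.
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type.
#' @param markers_per_type marker genes per type.
#' @param n_housekeeping stably expressed genes shared by all types.
#' @param n_background low, uniformly expressed filler genes.
#' @param detection_high,detection_low target within-type detection rates of
#'   a marker gene in its own vs other types.
#' @param theta NB size parameter used throughout.
#' @param seed integer seed.
#' @return List with \code{counts} (a \code{count_matrix} with
#'   \code{cell_type} metadata), \code{markers} (named list type -> marker
#'   gene ids), \code{housekeeping} and \code{background} gene id vectors.
#' @export
simulate_celltypes <- function(n_types = 3, cells_per_type = 300,
                               markers_per_type = 25, n_housekeeping = 100,
                               n_background = 300, detection_high = 0.9,
                               detection_low = 0.05, theta = 2, seed = 1) {
  stopifnot(n_types >= 1, detection_high > detection_low,
            detection_low >= 0, detection_high <= 1)
  # NB mean with P(X > 0) = target detection, given size theta:
  # P(X = 0) = (theta / (theta + mu))^theta  =>  solve for mu
  mu_for_detection <- function(p) theta * ((1 - p)^(-1 / theta) - 1)
  mu_hi <- mu_for_detection(detection_high)
  mu_lo <- mu_for_detection(detection_low)
  with_seed(seed, {
    types <- paste0("T", seq_len(n_types))
    G <- n_types * markers_per_type + n_housekeeping + n_background
    C <- n_types * cells_per_type
    type_of_cell <- rep(types, each = cells_per_type)
    ids_of <- function(prefix, n)
      if (n > 0) paste0(prefix, seq_len(n)) else character(0)
    gene_ids <- c(
      unlist(lapply(types, function(ty)
        ids_of(paste0("mk_", ty, "_"), markers_per_type))),
      ids_of("hk_", n_housekeeping),
      ids_of("bg_", n_background))
    vals <- matrix(0, G, C)
    row <- 0
    markers <- list()
    for (ty in types) {
      idx <- row + seq_len(markers_per_type)
      own <- type_of_cell == ty
      vals[idx, own] <- stats::rnbinom(markers_per_type * sum(own),
                                       size = theta, mu = mu_hi)
      vals[idx, !own] <- stats::rnbinom(markers_per_type * sum(!own),
                                        size = theta, mu = mu_lo)
      markers[[ty]] <- gene_ids[idx]
      row <- row + markers_per_type
    }
    hk_idx <- row + seq_len(n_housekeeping)
    # housekeeping: moderately high, identical across types
    hk_mu <- stats::runif(n_housekeeping, mu_for_detection(0.6),
                          mu_for_detection(0.95))
    vals[hk_idx, ] <- stats::rnbinom(n_housekeeping * C, size = theta,
                                     mu = rep(hk_mu, times = C))
    bg_idx <- row + n_housekeeping + seq_len(n_background)
    bg_mu <- stats::runif(n_background, mu_for_detection(0.02),
                          mu_for_detection(0.3))
    vals[bg_idx, ] <- stats::rnbinom(n_background * C, size = theta,
                                     mu = rep(bg_mu, times = C))
    cell_ids <- paste0("cell", seq_len(C))
    meta <- data.frame(cell_id = cell_ids, cell_type = type_of_cell,
                       stringsAsFactors = FALSE)
    counts <- count_matrix(vals, gene_ids, cell_ids, cell_meta = meta)
    list(counts = counts, markers = markers,
         housekeeping = gene_ids[hk_idx], background = gene_ids[bg_idx])
  })
}

#' The 96-setting simulation grid
#'
#' Cartesian grid of samples per group (2, 3, 5, 8) x cells per sample
#' (25, 50, 100, 200) x DE fraction (0.05, 0.1) x |log2 FC| (0.5, 1, 2):
#' 4 x 4 x 2 x 3 = 96 unique settings. Running each with \code{n_seeds}
#' seeds yields \code{96 * n_seeds} simulated datasets.
#'
#' @param n_genes genes per simulated dataset (kept modest so a full sweep
#'   stays cheap).
#' @param n_seeds seeds per setting (default 10, giving 960 datasets).
#' @param base_seed offset from which per-dataset seeds are derived.
#' @return List of \code{sim_config} objects of length
#'   \code{96 * n_seeds}; each carries \code{setting_id} and \code{rep}
#'   attributes. With \code{n_seeds = 1} the 96 unique settings themselves.
#' @export
setting_grid <- function(n_genes = 500, n_seeds = 1, base_seed = 1000) {
  grid <- expand.grid(samples_per_group = c(2, 3, 5, 8),
                      cells_per_sample = c(25, 50, 100, 200),
                      p_de = c(0.05, 0.1),
                      lfc = c(0.5, 1, 2))
  out <- list()
  n <- 0
  for (rep_i in seq_len(n_seeds)) {
    for (i in seq_len(nrow(grid))) {
      n <- n + 1
      cfg <- sim_config(n_genes = n_genes,
                        samples_per_group = grid$samples_per_group[i],
                        cells_per_sample = grid$cells_per_sample[i],
                        p_de = grid$p_de[i], lfc = grid$lfc[i],
                        seed = base_seed + n)
      attr(cfg, "setting_id") <- i
      attr(cfg, "rep") <- rep_i
      out[[n]] <- cfg
    }
  }
  out
}
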