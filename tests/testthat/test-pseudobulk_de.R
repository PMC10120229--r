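make_pb <- function(values, condition, mode = "detection_rate") {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("g", seq_len(ncol(values)))
  structure(list(values = values, mode = mode,
                 sample_ids = paste0("s", seq_len(nrow(values))),
                 condition = condition,
                 n_cells = rep(10, nrow(values))),
            class = "pseudobulk_table")
}

test_that("pseudobulk aggregation averages per sample in both modes", {
  vals <- cbind(c(0, 1), c(2, 0), c(4, 3), c(0, 0))
  m <- count_matrix(vals, c("g1", "g2"), paste0("c", 1:4))
  soc <- c("s1", "s1", "s1", "s2")
  pb <- aggregate_pseudobulk(m, soc, "detection_rate")
  expect_equal(pb$values["s1", "g1"], 2 / 3)
  expect_equal(pb$values["s2", "g1"], 0)
  expect_equal(pb$n_cells, c(3, 1))
  # all-detected gene has rate 1
  pb2 <- aggregate_pseudobulk(count_matrix(matrix(1, 1, 3)),
                              rep("s1", 3), "detection_rate")
  expect_equal(unname(pb2$values[1, 1]), 1)
  # detection_rate mode == mean mode on the binarized matrix, exactly
  mm <- random_count_matrix(12, 10, 1.5, seed = 6)
  soc2 <- rep(c("a", "b"), 5)
  b <- binarize(mm)
  expect_equal(aggregate_pseudobulk(mm, soc2, "detection_rate")$values,
               aggregate_pseudobulk(b, soc2, "mean")$values)
  expect_error(aggregate_pseudobulk(mm, rep("a", 3), "mean"), "per cell")
})

test_that("conditions attach to samples from metadata and must be unambiguous", {
  sim <- simulate_multisample(sim_config(n_genes = 30, samples_per_group = 2,
                                         cells_per_sample = 10, seed = 2))
  pb <- aggregate_pseudobulk(binarize(sim$counts), mode = "detection_rate")
  expect_equal(sort(unique(pb$condition)), c("A", "B"))
  expect_equal(length(pb$sample_ids), 4)
})

test_that("detection-rate Welch t matches the hand computation", {
  pb <- make_pb(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 6, 1),
                rep(c("A", "B"), each = 3))
  r <- de_test(pb, "detection_t")
  expect_equal(abs(r$stat), 3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-3.674235, 4), tolerance = 1e-6)
  expect_equal(r$effect, 0.3)
  # cross-check against t.test
  tt <- t.test(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate genes follow the stated rules", {
  pb <- make_pb(cbind(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)),
                rep(c("A", "B"), each = 3))
  r <- suppressWarnings(de_test(pb, "detection_t"))
  expect_equal(r$p[1], 1)  # identical groups
  expect_equal(r$effect[1], 0)
  # constant within both groups: no within-group replication, no inference
  expect_equal(r$p[2], 1)
  expect_error(de_test(make_pb(matrix(0.5, 3, 1), c("A", "A", "B"))),
               "2 samples")
  expect_error(de_test(make_pb(matrix(0.5, 4, 1), rep("A", 4))),
               "two conditions")
})

test_that("moderated trend with d0 = 0 collapses to the ordinary pooled t-test", {
  set.seed(41)
  vals <- matrix(rnorm(8 * 50, mean = 5), 8, 50)
  pb <- make_pb(vals, rep(c("A", "B"), each = 4), mode = "mean")
  r0 <- de_test(pb, "moderated_trend", d0_override = 0)
  ref <- apply(vals, 2, function(x)
    t.test(x[5:8], x[1:4], var.equal = TRUE)$statistic)
  expect_equal(r0$stat, unname(ref), tolerance = 1e-8)
  expect_equal(unique(r0$df), 6)
})

test_that("moderated trend shrinks variances toward the trend and tracks limma", {
  skip_if_not_installed("limma")
  set.seed(42)
  G <- 200
  means <- runif(G, 2, 8)
  vals <- sapply(seq_len(G), function(g)
    rnorm(8, mean = means[g] + c(0, 0, 0, 0, 1, 1, 1, 1) * (g <= 20) * 0.8,
          sd = 0.2 + 0.05 * means[g]))
  pb <- make_pb(vals, rep(c("A", "B"), each = 4), mode = "mean")
  ours <- de_test(pb, "moderated_trend")
  design <- cbind(1, rep(c(0, 1), each = 4))
  fit <- limma::eBayes(limma::lmFit(t(vals), design), trend = TRUE)
  # same test conception: moderated t statistics nearly proportional
  expect_gt(cor(ours$stat, fit$t[, 2]), 0.99)
  # moderated df exceeds the residual df when shrinkage happens
  expect_gt(unique(ours$df), 6)
})

test_that("BH adjustment matches the hand example and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
})

test_that("confusion summaries match the worked arithmetic", {
  genes <- paste0("g", 1:100)
  truth <- data.frame(gene = genes, is_de = c(rep(TRUE, 10), rep(FALSE, 90)))
  r <- structure(data.frame(gene = genes, effect = 0, stat = 0, df = 1,
                            p = 1, padj = 1,
                            call = c(rep(TRUE, 8), FALSE, FALSE,
                                     rep(TRUE, 4), rep(FALSE, 86))),
                 class = c("de_result", "data.frame"))
  gd <- setNames(rep(c(0.05, 0.95), 50), genes)
  ev <- evaluate_de(r, truth, gd)
  expect_equal(c(ev$TP, ev$FP, ev$FN, ev$TN), c(8, 4, 2, 86))
  expect_equal(ev$f1, 2 * (8 / 12) * (8 / 10) / ((8 / 12) + (8 / 10)))
  expect_equal(sum(ev$fn_by_detection_bin), 2)

  r$call <- rep(FALSE, 100)
  ev0 <- evaluate_de(r, truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$f1, 0)
  r$call <- truth$is_de
  evp <- evaluate_de(r, truth)
  expect_equal(c(evp$f1, evp$FP, evp$FN), c(1, 0, 0))
  expect_error(evaluate_de(r, data.frame(gene = "x", is_de = TRUE)),
               "gene sets")
})

test_that("a sample's detection-rate profile tracks its mean profile", {
  sim <- simulate_multisample(sim_config(seed = 3))
  norm <- normalize_log_cp10k(sim$counts)
  pb_mean <- aggregate_pseudobulk(norm, mode = "mean")
  pb_det <- aggregate_pseudobulk(binarize(sim$counts),
                                 mode = "detection_rate")
  rhos <- sapply(seq_len(nrow(pb_mean$values)), function(s)
    cor(pb_mean$values[s, ], pb_det$values[s, ], method = "spearman"))
  expect_gte(min(rhos), 0.95)
})

test_that("detection-rate t-test holds its type-I error on null simulations", {
  # two null datasets at 8 samples/group (enough replicates for the
  # t-approximation to hold), 3000 gene-tests in total
  ps <- unlist(lapply(1:2, function(i) {
    sim <- simulate_multisample(sim_config(n_genes = 1500,
                                           samples_per_group = 8,
                                           cells_per_sample = 50,
                                           p_de = 0, seed = 100 + i))
    pb <- aggregate_pseudobulk(binarize(sim$counts), mode = "detection_rate")
    suppressWarnings(de_test(pb, "detection_t"))$p
  }))
  rate <- mean(ps <= 0.05)
  n <- length(ps)
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("at very small group sizes the t-test errs only on the conservative side", {
  sim <- simulate_multisample(sim_config(n_genes = 1500,
                                         samples_per_group = 3,
                                         cells_per_sample = 50,
                                         p_de = 0, seed = 103))
  pb <- aggregate_pseudobulk(binarize(sim$counts), mode = "detection_rate")
  p <- suppressWarnings(de_test(pb, "detection_t"))$p
  rate <- mean(p <= 0.05)
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / length(p)))
})
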