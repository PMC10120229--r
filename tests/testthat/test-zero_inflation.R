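test_that("Poisson and ZIP fits match closed-form and grid-search oracles", {
  f <- suppressWarnings(fit_count_models(c(2, 2, 2, 2)))
  expect_equal(f$params$poisson$lambda, 2)
  expect_equal(unname(f$loglik["poisson"]),
               sum(dpois(rep(2, 4), 2, log = TRUE)), tolerance = 1e-12)

  x <- c(0, 0, 0, 0, 2, 2, 2, 2)
  f2 <- suppressWarnings(fit_count_models(x))
  # ZIP MLE: lambda solves lambda / (1 - exp(-lambda)) = mean of positives
  lam_root <- uniroot(function(l) l / (1 - exp(-l)) - 2, c(0.5, 3),
                      tol = 1e-10)$root
  expect_equal(f2$params$zip$lambda, lam_root, tolerance = 1e-4)
  pi_expect <- (0.5 - exp(-lam_root)) / (1 - exp(-lam_root))
  expect_equal(f2$params$zip$pi, pi_expect, tolerance = 1e-4)
  # dense grid-search oracle over (pi, lambda)
  grid <- expand.grid(pi = seq(0, 0.9, 0.002), lambda = seq(0.2, 4, 0.002))
  ll <- with(grid, {
    p0 <- pi + (1 - pi) * exp(-lambda)
    4 * log(p0) + 4 * (log(1 - pi) + dpois(2, lambda, log = TRUE))
  })
  best <- grid[which.max(ll), ]
  expect_equal(f2$params$zip$lambda, best$lambda, tolerance = 0.01)
  expect_equal(f2$params$zip$pi, best$pi, tolerance = 0.01)
  expect_gte(unname(f2$loglik["zip"]), max(ll) - 1e-6)
})

test_that("model nesting holds at the optima and inputs are validated", {
  set.seed(51)
  for (i in 1:10) {
    x <- rnbinom(60, mu = runif(1, 0.5, 4), size = runif(1, 0.3, 3))
    x[seq_len(20)] <- x[seq_len(20)] * rbinom(20, 1, 0.5)  # extra zeros
    if (all(x == 0)) next
    f <- suppressWarnings(fit_count_models(x))
    expect_gte(unname(f$loglik["nbinom"]), unname(f$loglik["poisson"]) - 1e-6)
    expect_gte(unname(f$loglik["zip"]), unname(f$loglik["poisson"]) - 1e-6)
    expect_gte(unname(f$loglik["zinb"]), unname(f$loglik["nbinom"]) - 1e-6)
    expect_true(f$params$zinb$pi >= 0 && f$params$zinb$pi < 1)
    expect_gt(f$params$nbinom$theta, 0)
    expect_equal(unname(f$bic),
                 unname(-2 * f$loglik + c(1, 2, 2, 3) * log(length(x))))
    expect_equal(f$zero_inflated, f$selected %in% c("zip", "zinb"))
  }
  expect_error(fit_count_models(rep(0, 30)), "all-zero")
  expect_error(fit_count_models(c(1, -1)), "non-negative")
  expect_warning(fit_count_models(c(1, 2, 3)), "fewer than 20")
})

test_that("NB fit recovers simulated parameters and matches MASS", {
  set.seed(52)
  rel_err <- replicate(50, {
    mu <- runif(1, 1, 8); theta <- runif(1, 0.5, 4)
    x <- rnbinom(2000, mu = mu, size = theta)
    f <- suppressWarnings(fit_count_models(x))
    max(abs(f$params$nbinom$mu - mu) / mu,
        abs(f$params$nbinom$theta - theta) / theta)
  })
  expect_lt(median(rel_err), 0.15)

  skip_if_not_installed("MASS")
  set.seed(53)
  x <- rnbinom(500, mu = 3, size = 1.5)
  f <- suppressWarnings(fit_count_models(x))
  ref <- suppressWarnings(MASS::fitdistr(x, "negative binomial"))
  expect_equal(f$params$nbinom$mu, unname(ref$estimate["mu"]),
               tolerance = 1e-4)
  expect_equal(f$params$nbinom$theta, unname(ref$estimate["size"]),
               tolerance = 1e-3)
})

test_that("two-proportion detection ranking matches the formula and modes", {
  # 100 cells per group; one gene at 0.9 vs 0.1, one flat at 0.5, one dead
  vals <- rbind(c(rep(1, 90), rep(0, 10), rep(1, 10), rep(0, 90)),
                rep(rep(c(1, 0), each = 50), 2),
                rep(0, 200))
  b <- binary_matrix(vals, c("de_gene", "flat_gene", "dead_gene"),
                     paste0("c", 1:200))
  grp <- rep(c("x", "y"), each = 100)
  de <- rank_genes_binary(b, grp, "de", 3)
  expect_equal(de$gene[1], "de_gene")
  expect_equal(de$z[1], 0.8 / sqrt(0.25 * 0.02), tolerance = 1e-10)
  st <- rank_genes_binary(b, grp, "stable", 3)
  expect_equal(st$gene[1], "flat_gene")
  expect_equal(st$z[st$gene == "flat_gene"], 0)
  expect_false("dead_gene" %in% st$gene)  # fails the 0.1 detection floor
  expect_error(rank_genes_binary(b, rep("x", 200), "de"), "two groups")
})

test_that("Fisher exact inference reproduces published 2x2 results", {
  r10x <- fisher_exact_2x2(c(99, 1, 35, 65))
  expect_equal(r10x$p_two_sided, 3.03e-25, tolerance = 0.005)
  expect_equal(r10x$log_or_cmle, 5.19, tolerance = 0.005)
  expect_equal(r10x$ci95_log, c(3.36, 8.87), tolerance = 0.005)

  rss <- fisher_exact_2x2(c(97, 3, 44, 56))
  expect_equal(rss$p_two_sided, 5.46e-18, tolerance = 0.005)
  expect_equal(rss$log_or_cmle, 3.70, tolerance = 0.005)
  expect_equal(rss$ci95_log, c(2.50, 5.36), tolerance = 0.005)
})

test_that("Fisher p matches brute-force enumeration and symmetry cases", {
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$p_two_sided, 1)
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$log_or_cmle, 0, tolerance = 1e-8)
  expect_equal(fisher_exact_2x2(c(3, 1, 1, 3))$p_two_sided, 34 / 70,
               tolerance = 1e-12)

  set.seed(54)
  for (i in 1:200) {
    repeat {
      tab <- matrix(rpois(4, sample(1:8, 1)), 2, 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) && sum(tab) <= 40)
        break
    }
    r <- fisher_exact_2x2(tab)
    expect_lt(abs(r$p_two_sided - fisher_p_enum(tab)), 1e-12)
    expect_true(r$ci95_log[1] <= r$log_or_cmle + 1e-8)
    expect_true(r$log_or_cmle <= r$ci95_log[2] + 1e-8)
  }
  expect_error(fisher_exact_2x2(c(0, 0, 1, 2)), "margin")
})

test_that("conditional-MLE log odds ratio is monotone in the observed cell", {
  lor <- sapply(1:9, function(x)
    fisher_exact_2x2(matrix(c(x, 10 - x, 10 - x, x), 2, 2))$log_or_cmle)
  expect_true(all(diff(lor) > 0))
})

test_that("zero-inflation enrichment builds the right table and flags misuse", {
  zi <- setNames(rep(c(TRUE, FALSE), c(12, 28)), paste0("g", 1:40))
  de <- paste0("g", 1:10)       # 10 ZI
  st <- paste0("g", 21:30)      # 0 ZI
  r <- zero_inflation_enrichment(zi, de, st)
  expect_equal(unname(r$table), rbind(c(10, 0), c(0, 10)))
  expect_gt(r$log_or_cmle, 0)
  expect_error(zero_inflation_enrichment(zi, de, c(st, "g5")), "overlap")
  expect_error(zero_inflation_enrichment(zi, c(de, "nope"), st), "without fits")

  # identical ZI fractions in both lists: no enrichment
  r0 <- zero_inflation_enrichment(zi, c(paste0("g", 1:5), paste0("g", 13:17)),
                                  c(paste0("g", 6:10), paste0("g", 18:22)))
  expect_equal(r0$log_or_cmle, 0, tolerance = 1e-8)
  expect_gt(r0$p_two_sided, 0.5)
})

test_that("marker genes fit zero-inflated, housekeeping genes do not, and the enrichment is positive", {
  sim <- simulate_celltypes(n_types = 3, cells_per_type = 100,
                            markers_per_type = 15, n_housekeeping = 30,
                            n_background = 0, seed = 55)
  pooled <- sim$counts$values
  # a marker pooled across types shows excess zeros vs its pooled-mean Poisson
  mk <- sim$markers[[1]][1]
  expect_gt(mean(pooled[mk, ] == 0), exp(-mean(pooled[mk, ])))

  genes <- c(unlist(sim$markers), sim$housekeeping)
  fits <- lapply(genes, function(g)
    suppressWarnings(fit_count_models(pooled[g, ])))
  names(fits) <- genes
  enr <- zero_inflation_enrichment(fits, unlist(sim$markers),
                                   sim$housekeeping)
  expect_gt(enr$log_or_cmle, 0)
  expect_lt(enr$p_two_sided, 0.01)
})
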