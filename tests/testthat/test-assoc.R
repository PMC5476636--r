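test_that("distance correlation hits its analytic anchors", {
  x <- c(0.1, 2, 3.5, 1, 0.7)
  expect_equal(dcor(x, 2 * x + 1), 1, tolerance = 1e-12)
  y <- c(5, 1, 0.2, 4, 2.2)
  # brute force via the three-sum V-statistic decomposition
  a <- as.matrix(dist(x)); b <- as.matrix(dist(y))
  S1 <- mean(a * b); S2 <- mean(a) * mean(b)
  S3 <- mean(rowMeans(a) * rowMeans(b))
  dvx <- mean(a * a) + mean(a)^2 - 2 * mean(rowMeans(a)^2)
  dvy <- mean(b * b) + mean(b)^2 - 2 * mean(rowMeans(b)^2)
  expect_equal(dcor(x, y), sqrt((S1 + S2 - 2 * S3) / sqrt(dvx * dvy)),
               tolerance = 1e-12)
  expect_equal(dcor(x, y), dcor(y, x))
  # affine invariance in either argument
  expect_equal(dcor(3 * x - 2, y), dcor(x, y), tolerance = 1e-12)
  expect_equal(dcor(x, -0.5 * y + 7), dcor(x, y), tolerance = 1e-12)
  expect_warning(z <- dcor(rep(1, 5), y), "constant")
  expect_equal(z, 0)
})

test_that("independent samples give small dcor relative to the permutation null", {
  set.seed(14)
  x <- runif(300); y <- runif(300)
  obs <- dcor(x, y)
  null <- vapply(1:60, function(i) dcor(sample(x), y), numeric(1))
  expect_lte(obs, quantile(null, 0.95) * 1.5)
  expect_lt(obs, 0.2)
})

test_that("KNN mutual information tracks the Gaussian closed form", {
  set.seed(2)
  n <- 2000; rho <- 0.9
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(knn_mi(x, y, 3, seed = 5), -0.5 * log(1 - rho^2),
               tolerance = 0.12)
  u <- runif(n); v <- runif(n)
  expect_lt(abs(knn_mi(u, v, 3, seed = 6)), 0.05)
  # self-information grows with sample size (monotone sanity)
  set.seed(9)
  small <- rnorm(200); large <- rnorm(1000)
  expect_gt(knn_mi(large, large, 3, seed = 1),
            knn_mi(small, small, 3, seed = 1))
  expect_error(knn_mi(1:3, 1:3, 5), "more observations")
})

test_that("a cyclic signal gene outranks noise genes by significance", {
  set.seed(30)
  T_ <- 150
  phase <- seq(0, 1, length.out = T_)
  vals <- matrix(abs(rnorm(24 * T_, 3, 1)), 24)
  vals[1, ] <- 3 + 2.5 * sin(2 * pi * phase) + rnorm(T_, 0, 0.8)
  vals <- pmax(vals, 0)
  dimnames(vals) <- list(c("signal", paste0("noise", 1:23)),
                         paste0("c", seq_len(T_)))
  mat <- toy_log2(vals)
  ord <- tibble::tibble(cell_id = colnames(vals), linear_rank = seq_len(T_))
  res <- rank_cycle_genes(mat, ord, n_perm = 49, seed = 2)
  expect_equal(res$gene_id[1], "signal")
  expect_equal(min(res$dcor_p), res$dcor_p[res$gene_id == "signal"])
  expect_gt(res$dcor_z[res$gene_id == "signal"],
            max(res$dcor_z[res$gene_id != "signal"]))
  expect_gt(res$dcor[res$gene_id == "signal"],
            max(res$dcor[res$gene_id != "signal"]))
  # shuffling the order destroys the advantage
  set.seed(4)
  shuf <- ord; shuf$linear_rank <- sample(shuf$linear_rank)
  res2 <- rank_cycle_genes(mat, shuf, n_perm = 49, seed = 2)
  expect_lt(res2$dcor[res2$gene_id == "signal"],
            res$dcor[res$gene_id == "signal"] / 2)
  # without permutations the statistics are still computed, p is missing
  res0 <- rank_cycle_genes(mat, ord, n_perm = 0, seed = 2)
  expect_true(all(is.na(res0$dcor_p)))
  expect_false(any(is.na(res0$dcor)))
  expect_equal(res0$gene_id[1], "signal")
})

test_that("permutation p-values are uniform under the null", {
  # the raw-series statistic is continuous, so exchangeability gives exact
  # uniformity; the smoothed path is valid but conservative (boundary-model
  # pruning collapses most null genes to a constant, tying their p-values)
  set.seed(55)
  T_ <- 80
  vals <- matrix(abs(rnorm(100 * T_, 3, 1)), 100)
  dimnames(vals) <- list(paste0("g", 1:100), paste0("c", seq_len(T_)))
  ord <- tibble::tibble(cell_id = colnames(vals), linear_rank = seq_len(T_))
  res <- rank_cycle_genes(toy_log2(vals), ord, n_perm = 39, seed = 7,
                          smooth = FALSE)
  ks <- suppressWarnings(stats::ks.test(res$dcor_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$dcor_p >= 0 & res$dcor_p <= 1))
  expect_true(all(res$dcor_q >= res$dcor_p - 1e-12))
})
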