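test_that("dense and MatrixMarket readers round-trip the same matrix", {
  vals <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("c1", "c2")))
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "m.tsv")
  readr::write_tsv(tibble::as_tibble(vals, rownames = "gene"), tsv)
  m1 <- read_expression(tsv, "tsv", "TPM")
  expect_equal(m1$values, vals)
  expect_equal(m1$layer, "raw")

  mtx <- file.path(dir, "m.mtx")
  Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE), mtx)
  writeLines(rownames(vals), file.path(dir, "genes.txt"))
  writeLines(colnames(vals), file.path(dir, "cells.txt"))
  m2 <- read_expression(mtx, "mtx", "TPM")
  expect_equal(m2$values, m1$values)

  # duplicate ids violate the container invariant
  readr::write_tsv(tibble::tibble(gene = c("gA", "gA"), c1 = c(1, 2),
                                  c2 = c(3, 4)), tsv)
  expect_error(read_expression(tsv, "tsv", "TPM"), "duplicate gene ids")
  expect_error(expr_matrix(matrix(-1, 1, 1, dimnames = list("g", "c"))),
               "negative")
})

test_that("cell QC keeps strictly-more-than cells and is idempotent", {
  # a cell with exactly min_genes genes above threshold is removed
  vals <- cbind(at_bound = c(rep(3, 4000), 0), above = rep(3, 4001))
  rownames(vals) <- paste0("g", seq_len(4001))
  m <- toy_expr(vals)
  res <- qc_filter_cells(m)
  expect_equal(cell_ids(res$mat), "above")
  expect_equal(res$report$cells_kept, 1L)

  toy <- toy_expr(cbind(four = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                        three = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)))
  kept <- qc_filter_cells(toy, min_genes = 3, min_expr = 0)
  expect_equal(cell_ids(kept$mat), "four")
  all_kept <- qc_filter_cells(toy, min_genes = 0, min_expr = 0)
  expect_equal(ncol(all_kept$mat$values), 2L)
  twice <- qc_filter_cells(kept$mat, min_genes = 3, min_expr = 0)
  expect_equal(twice$mat$values, kept$mat$values)
  expect_error(qc_filter_cells(toy, min_genes = 9, min_expr = 0),
               "no eligible cells")
})

test_that("gene QC boundary is inclusive", {
  m <- toy_expr(rbind(boundary = c(2, 2, 2), low = c(0, 0, 3),
                      high = c(5, 5, 5)))
  f <- qc_filter_genes(m, min_mean = 2)
  expect_setequal(gene_ids(f), c("boundary", "high"))
  expect_equal(gene_ids(qc_filter_genes(m, min_mean = 0)), gene_ids(m))
  expect_error(qc_filter_genes(m, min_mean = 100), "no genes left")
})

test_that("size factors follow the median-of-ratios definition", {
  # all cells identical -> unit factors
  m <- toy_expr(matrix(c(2, 5, 2, 5, 2, 5), 2,
                       dimnames = list(c("g1", "g2"), c("a", "b", "c"))))
  expect_equal(unname(deseq_size_factors(m)), rep(1, 3))

  # one-gene matrix (4, 9): geometric mean 6, factors 4/6 and 9/6
  m1 <- toy_expr(matrix(c(4, 9), 1, dimnames = list("g", c("a", "b"))))
  expect_equal(unname(deseq_size_factors(m1)), c(4 / 6, 9 / 6))

  # doubling a column doubles its factor; ratio preserved exactly
  set.seed(3)
  v <- matrix(rpois(40, 20) + 1, 8)
  dimnames(v) <- list(paste0("g", 1:8), paste0("c", 1:5))
  sA <- deseq_size_factors(toy_expr(v))
  v2 <- v; v2[, 2] <- 2 * v2[, 2]
  sB <- deseq_size_factors(toy_expr(v2))
  expect_equal(unname(sB[2] / sA[2]), unname(2 * (sB[1] / sA[1])),
               tolerance = 1e-12)
  # normalized matrices identical regardless of the scaling
  n1 <- normalize_expression(toy_expr(v))$values
  n2 <- normalize_expression(toy_expr(v2))$values
  expect_equal(n1 / n1[1, 1], n2 / n2[1, 1], tolerance = 1e-12)

  zero <- toy_expr(rbind(g1 = c(0, 1), g2 = c(1, 0)))
  expect_error(deseq_size_factors(zero), "relax the gene QC")
})

test_that("log transform hits its fixed points and is strictly monotone", {
  m <- toy_expr(matrix(c(0, 1, 3, 7), 2,
                       dimnames = list(c("g1", "g2"), c("a", "b"))),
                layer = "raw")
  lt <- log_transform(m)
  expect_equal(lt$values, matrix(c(0, 1, 2, 3), 2,
                                 dimnames = dimnames(m$values)))
  expect_equal(lt$layer, "log2")
  expect_error(log_transform(lt), "already log2")
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(log2(x + 1)) > 0))
})

test_that("catalog subsetting preserves order and rejects empty overlap", {
  m <- toy_expr(matrix(1:10, 5, dimnames = list(paste0("g", 5:1),
                                                c("a", "b"))))
  cat3 <- gene_catalog(tibble::tibble(gene_id = c("g1", "g3", "g4"),
                                      peak_stage = c("G1", "S", "M"),
                                      rank = 1:3))
  sub <- subset_to_catalog(m, cat3)
  expect_equal(gene_ids(sub), c("g4", "g3", "g1"))   # matrix order kept
  all_cat <- gene_catalog(tibble::tibble(gene_id = paste0("g", 1:5),
                                         peak_stage = "G1", rank = 1:5))
  expect_equal(subset_to_catalog(m, all_cat)$values, m$values)
  disjoint <- gene_catalog(tibble::tibble(gene_id = "zzz", peak_stage = "G1",
                                          rank = 1L))
  expect_error(subset_to_catalog(m, disjoint), "no catalog genes")
  # case-insensitive fallback is opt-in
  upper <- gene_catalog(tibble::tibble(gene_id = "G1", peak_stage = "G1",
                                       rank = 1L))
  expect_error(subset_to_catalog(m, upper))
  expect_equal(gene_ids(subset_to_catalog(m, upper, ignore_case = TRUE)), "g1")
})
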