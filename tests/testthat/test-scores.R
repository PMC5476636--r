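make_pair_model <- function(gene_a, gene_b, probs) {
  structure(list(pairs = tibble::tibble(gene_a = gene_a, gene_b = gene_b),
                 probs = probs,
                 priors = stats::setNames(rep(1 / 3, 3), c("G1", "S", "G2M")),
                 n_pairs = length(gene_a), stages = c("G1", "S", "G2M")),
            class = "gene_pair_model")
}

test_that("pair training reproduces hand-counted Laplace-smoothed frequencies", {
  # 12 cells, 4 per stage; pair (gA, gB): gA >= gB in 3/4 G1 cells,
  # 1/4 S cells, 0/4 G2M cells
  gA <- c(5, 5, 5, 1,  1, 1, 1, 5,  1, 1, 1, 1)
  gB <- rep(3, 12)
  filler <- rbind(seq(0.1, 1.2, by = 0.1), seq(1.2, 0.1, by = -0.1))
  v <- rbind(gA = gA, gB = gB, f1 = filler[1, ], f2 = filler[2, ])
  colnames(v) <- paste0("c", 1:12)
  labels <- rep(c("G1", "S", "G2M"), each = 4)
  model <- suppressWarnings(train_gene_pairs(toy_log2(v), labels,
                                             pairs_per_stage = 4))
  i <- which(model$pairs$gene_a == "gA" & model$pairs$gene_b == "gB")
  expect_length(i, 1)
  expect_equal(unname(model$probs[i, "G1"]), (3 + 1) / (4 + 2))
  expect_equal(unname(model$probs[i, "S"]), (1 + 1) / (4 + 2))
  expect_equal(unname(model$probs[i, "G2M"]), (0 + 1) / (4 + 2))
})

test_that("uninformative pairs are never selected and ranks drive selection", {
  # gC >= gD in every cell of every stage: margin 0 everywhere
  v <- rbind(gC = rep(9, 6), gD = rep(1, 6),
             gE = c(5, 5, 1, 1, 1, 1), gF = c(3, 3, 3, 3, 3, 3))
  colnames(v) <- paste0("c", 1:6)
  labels <- rep(c("G1", "S", "G2M"), each = 2)
  model <- suppressWarnings(train_gene_pairs(toy_log2(v), labels,
                                             pairs_per_stage = 2))
  expect_false(any(model$pairs$gene_a == "gC" & model$pairs$gene_b == "gD"))
  # training depends only on within-cell comparisons: a per-cell monotone
  # transform changes nothing
  v2 <- sweep(v, 2, c(1, 2, 0.5, 3, 1.5, 2.5), "*")
  model2 <- suppressWarnings(train_gene_pairs(toy_log2(v2), labels,
                                              pairs_per_stage = 2))
  expect_equal(model$pairs, model2$pairs)
  expect_equal(model$probs, model2$probs)
})

test_that("Bayes scores implement the Bernoulli product with uniform prior", {
  # uninformative model: every score equals Np*log10(1/2) + log10(1/3)
  m0 <- make_pair_model(c("a", "b"), c("b", "c"),
                        matrix(0.5, 2, 3,
                               dimnames = list(NULL, c("G1", "S", "G2M"))))
  e <- c(a = 3, b = 2, c = 1)
  sc <- bayes_scores(m0, e)
  expect_equal(unname(sc), rep(2 * log10(0.5) + log10(1 / 3), 3))

  # hand computation: p = (0.9, 0.8) for G1, x = (1, 1)
  probs <- cbind(G1 = c(0.9, 0.8), S = c(0.5, 0.5), G2M = c(0.2, 0.3))
  m1 <- make_pair_model(c("a", "b"), c("b", "c"), probs)
  sc1 <- bayes_scores(m1, e)
  expect_equal(unname(sc1["G1"]), log10(0.9 * 0.8 * (1 / 3)))
  expect_true(all(sc1 <= log10(1 / 3) + 1e-12))
  # permutation invariance of the pair order
  m2 <- make_pair_model(c("b", "a"), c("c", "b"), probs[2:1, ])
  expect_equal(bayes_scores(m2, e), sc1)
  expect_error(bayes_scores(m1, c(a = 1, b = 2)), "lacks gene")
})

test_that("mean scores average their own set and ignore the rest", {
  catalog <- gene_catalog(tibble::tibble(
    gene_id = paste0("g", 1:12),
    peak_stage = rep(c("G1", "G1/S", "S", "G2", "G2/M", "M"), 2),
    rank = 1:12))
  sets <- mean_score_sets(catalog)
  e <- stats::setNames(rep(0, 12), paste0("g", 1:12))
  expect_equal(unname(mean_scores(e, sets)), rep(0, 6))
  e["g1"] <- 2; e["g7"] <- 4           # both peak at G1
  ms <- mean_scores(e, sets)
  expect_equal(unname(ms["G1"]), 3)
  # doubling a disjoint stage's genes leaves G1 untouched
  e2 <- e; e2[c("g3", "g9")] <- e2[c("g3", "g9")] + 10
  expect_equal(mean_scores(e2, sets)["G1"], ms["G1"])
  # absent genes are skipped with a warning; an emptied set errors
  expect_warning(mean_scores(e[-1], sets), "absent")
  expect_error(suppressWarnings(mean_scores(e[-c(1, 7)], sets)),
               "no genes of stage set")
})

test_that("score tracks follow the ordering and reverse with it", {
  sim <- quick_sim(21, n_cells = 50, n_genes = 60)
  ord <- consensus_order(sim$log2, k_min = 4, k_max = 6, n_fold = 1,
                         seed = 3, n_init = 2)
  lab <- stats::setNames(ifelse(sim$truth$stage == "G0", "G1",
                                sim$truth$stage), sim$truth$cell_id)
  model <- suppressWarnings(train_gene_pairs(sim$log2, lab[cell_ids(sim$log2)],
                                             pairs_per_stage = 30))
  sets <- mean_score_sets(sim$catalog)
  tr <- score_track(ord, sim$log2, model, sets)
  expect_equal(nrow(tr), 50)
  expect_equal(tr$rank, 1:50)
  rev_ord <- relinearize(ord, reverse = TRUE)
  tr_rev <- score_track(rev_ord, sim$log2, model, sets)
  m <- match(tr$cell_id, tr_rev$cell_id)
  expect_equal(as.matrix(tr[, cyclotour:::score_columns]),
               as.matrix(tr_rev[m, cyclotour:::score_columns]))
  # cluster granularity: members of one cluster share their scores
  cl <- stats::setNames(rep(c("a", "b"), length.out = 50), tr$cell_id)
  trc <- score_track(ord, sim$log2, model, sets, granularity = "cluster",
                     clusters = cl)
  grp <- split(trc$bayes_G1, cl[trc$cell_id])
  expect_true(all(vapply(grp, function(x) diff(range(x)) == 0, logical(1))))
})

test_that("gene-pair models survive a JSON round trip", {
  probs <- cbind(G1 = c(0.9, 0.8), S = c(0.5, 0.5), G2M = c(0.2, 0.3))
  m <- make_pair_model(c("a", "b"), c("b", "c"), probs)
  path <- withr::local_tempfile(fileext = ".json")
  write_gene_pair_model(m, path)
  m2 <- read_gene_pair_model(path)
  e <- c(a = 3, b = 2, c = 1)
  expect_equal(bayes_scores(m2, e), bayes_scores(m, e), tolerance = 1e-12)
})
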