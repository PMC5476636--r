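test_that("noiseless block emissions are recovered exactly", {
  obs <- matrix(rep(c(0, 5, 10), times = c(8, 8, 8)), ncol = 1)
  fit <- suppressWarnings(fit_hmm(obs, include_g0 = FALSE, max_iter = 200))
  expect_equal(sort(fit$means[, 1]), c(0, 5, 10), tolerance = 1e-6,
               ignore_attr = TRUE)
  v <- viterbi_stages(fit, obs)
  expect_equal(as.integer(v$stage), rep(1:3, each = 8))
  expect_true(all(diff(as.integer(v$stage)) >= 0))   # left-to-right
})

test_that("forward likelihood matches exhaustive path enumeration", {
  hmm <- toy_hmm2()
  set.seed(4)
  for (n in c(2, 3, 5)) {
    obs <- matrix(rnorm(n, 1.5, 2), ncol = 1)
    expect_equal(hmm_loglik(hmm, obs), brute_forward(hmm, obs),
                 tolerance = 1e-10)
  }
})

test_that("Viterbi matches exhaustive argmax and dominates alternatives", {
  hmm <- toy_hmm2(stay = 0.6)
  set.seed(11)
  for (rep in 1:4) {
    obs <- matrix(rnorm(4, 1.5, 2.5), ncol = 1)
    v <- viterbi_stages(hmm, obs)
    brute <- brute_viterbi(hmm, obs)
    expect_equal(as.integer(v$stage), brute$path)
    expect_equal(attr(v, "path_loglik"), brute$loglik, tolerance = 1e-10)
    # any user-supplied valid path scores no better
    alt <- c(1L, 1L, 2L, 2L)
    lp_alt <- sum(log(hmm$A[cbind(alt[-4], alt[-1])])) +
      sum(stats::dnorm(obs, hmm$means[alt, 1], sqrt(hmm$variances[alt, 1]),
                       log = TRUE))
    expect_gte(attr(v, "path_loglik"), lp_alt - 1e-12)
  }
})

test_that("Baum-Welch log-likelihood is monotone and structure is conserved", {
  tr <- sim_score_track(rep(c("G1", "S", "G2M"), times = c(15, 12, 13)),
                        seed = 3)
  fit <- suppressWarnings(fit_hmm(tr, include_g0 = FALSE))
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  A <- fit$A
  off <- A
  for (i in seq_len(nrow(A))) off[i, i:min(i + 1, ncol(A))] <- 0
  expect_equal(sum(off), 0)
  expect_equal(rowSums(A), rep(1, 3), ignore_attr = TRUE)
})

test_that("start search is equivariant to input rotation", {
  tr <- sim_score_track(rep(c("G1", "S", "G2M"), times = c(10, 10, 10)),
                        seed = 6, sd = 0.2)
  s0 <- find_start(tr, refit = FALSE)
  expect_equal(s0$rotation, 0)
  expect_equal(s0$orientation, 1)
  n <- nrow(tr)
  r <- 7L
  rot <- tr
  rot[, cyclotour:::score_columns] <-
    tr[cyclotour:::circular_index(n, r, 1L), cyclotour:::score_columns]
  s1 <- find_start(rot, refit = FALSE)
  expect_equal(s1$rotation, (s0$rotation - r) %% n)
  expect_equal(s1$likelihood, s0$likelihood, tolerance = 1e-6)
})

test_that("stage accuracy is high on separated synthetic tracks", {
  truth <- rep(c("G1", "S", "G2M"), times = c(200, 150, 150))
  tr <- sim_score_track(truth, seed = 9, sd = 0.5)
  s <- find_start(tr, refit = FALSE)
  path <- viterbi_stages(s$hmm, tr, s$rotation, s$orientation)
  acc <- mean(as.character(path$stage) ==
                truth[match(path$cell_id, tr$cell_id)])
  expect_gte(acc, 0.9)
})

test_that("a G0 arc with depressed mean-scores favours the 4-state model", {
  truth <- rep(c("G0", "G1", "S", "G2M"), times = c(20, 25, 20, 25))
  tr <- sim_score_track(truth, seed = 12, sd = 0.3)
  f3 <- suppressWarnings(fit_hmm(tr, include_g0 = FALSE))
  f4 <- suppressWarnings(fit_hmm(tr, include_g0 = TRUE))
  expect_gt(f4$log_likelihood, f3$log_likelihood)
  path <- viterbi_stages(f4, tr)
  acc <- mean(as.character(path$stage) ==
                truth[match(path$cell_id, tr$cell_id)])
  expect_gte(acc, 0.9)
})

test_that("stage proportions tally correctly per group", {
  hmm <- toy_hmm2()
  obs <- matrix(c(-0.2, 0.1, 3.2, 2.9), ncol = 1)
  path <- viterbi_stages(hmm, obs)
  p1 <- stage_proportions(path)
  expect_equal(sum(p1$prop), 1)
  groups <- stats::setNames(c("x", "x", "y", "y"), path$cell_id)
  p2 <- stage_proportions(path, groups)
  expect_equal(p2$prop[p2$group == "x" & p2$stage == "G1"], 1)
  expect_equal(p2$prop[p2$group == "y" & p2$stage == "S"], 1)
  expect_equal(as.numeric(tapply(p2$prop, p2$group, sum)), c(1, 1))
})

test_that("hand-set models reject illegal transition structure", {
  A_bad <- matrix(c(0.5, 0.2, 0.3, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE,
                  dimnames = list(c("G1", "S", "G2M"), c("G1", "S", "G2M")))
  expect_error(make_cycle_hmm(matrix(0, 3, 1), matrix(1, 3, 1), A_bad),
               "outside self/successor")
})
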