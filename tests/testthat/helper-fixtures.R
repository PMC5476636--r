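# small in-code fixtures shared across test files

toy_expr <- function(values, unit = "TPM", layer = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(ncol(values)))
  expr_matrix(values, unit = unit, layer = layer)
}

# log2-layer matrix straight from values (bypassing normalization)
toy_log2 <- function(values) toy_expr(values, layer = "log2")

# a quick cyclic simulation preprocessed to the log2 layer
quick_sim <- function(seed, n_cells = 120, n_genes = 80, ...) {
  cfg <- cycle_sim_config(n_cells = n_cells, n_genes = n_genes, seed = seed, ...)
  sim <- simulate_expression(cfg)
  prep <- suppressWarnings(preprocess_expression(
    sim$mat, catalog = sim$catalog, min_genes = 10, min_expr = 0.5,
    min_mean = 2))
  sim$log2 <- prep$mat
  sim
}

# exhaustive TSP optimum: all (k-1)!/2 distinct cycles
brute_tour_length <- function(D) {
  k <- nrow(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  best <- Inf
  for (p in perms(2:k)) best <- min(best, tour_length(c(1L, p), D))
  best
}

# forward likelihood by exhaustive path enumeration (start state fixed to 1)
brute_forward <- function(hmm, obs) {
  N <- length(hmm$states); n <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    if (s[1] != 1L) next
    p <- 1
    for (t in seq_len(n)) {
      if (t > 1) p <- p * hmm$A[s[t - 1], s[t]]
      p <- p * prod(stats::dnorm(obs[t, ], hmm$means[s[t], ],
                                 sqrt(hmm$variances[s[t], ])))
    }
    total <- total + p
  }
  log(total)
}

# best path by exhaustive enumeration
brute_viterbi <- function(hmm, obs) {
  N <- length(hmm$states); n <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    if (s[1] != 1L) next
    lp <- 0
    for (t in seq_len(n)) {
      if (t > 1) {
        a <- hmm$A[s[t - 1], s[t]]
        if (a == 0) { lp <- -Inf; break }
        lp <- lp + log(a)
      }
      lp <- lp + sum(stats::dnorm(obs[t, ], hmm$means[s[t], ],
                                  sqrt(hmm$variances[s[t], ]), log = TRUE))
    }
    if (lp > best) { best <- lp; best_path <- s }
  }
  list(path = unname(best_path), loglik = best)
}

# a hand-set 2-state left-to-right toy HMM over 1-dim emissions
toy_hmm2 <- function(stay = 0.7) {
  make_cycle_hmm(means = matrix(c(0, 3)), variances = matrix(c(1, 1)),
                 A = matrix(c(stay, 1 - stay, 0, 1), 2, byrow = TRUE,
                            dimnames = list(c("G1", "S"), c("G1", "S"))))
}

# synthetic score track from a known stage sequence with separated means
sim_score_track <- function(stage_seq, seed = 1, sd = 0.3) {
  set.seed(seed)
  stages <- c("G1", "S", "G2M")
  # anchored emission profiles: own-stage Bayes score high, mean-scores
  # shaped per stage family
  profiles <- rbind(
    G1  = c(-2, -8, -8, 3.0, 2.0, 1.0, 1.0, 1.0, 1.5),
    S   = c(-8, -2, -8, 1.0, 2.5, 3.0, 1.5, 1.0, 1.0),
    G2M = c(-8, -8, -2, 1.0, 1.0, 1.5, 2.5, 3.0, 2.5),
    G0  = c(-4, -7, -7, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2))
  obs <- profiles[stage_seq, , drop = FALSE] +
    matrix(rnorm(9 * length(stage_seq), 0, sd), ncol = 9)
  colnames(obs) <- c("bayes_G1", "bayes_S", "bayes_G2M", "mean_G1",
                     "mean_G1S", "mean_S", "mean_G2", "mean_G2M", "mean_M")
  tibble::as_tibble(obs) |>
    dplyr::mutate(cell_id = paste0("c", dplyr::row_number()),
                  rank = dplyr::row_number())
}
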