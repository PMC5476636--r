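#' Distance correlation
#'
#' Nonlinear association between two equal-length series, from the
#' doubly-centered pairwise distance matrices (the V-statistic form): zero
#' iff independence in the population, 1 for exact affine dependence.
#' Constant inputs have no defined value and return 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return distance correlation in `[0, 1]`.
#' @export
dcor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: distance correlation undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  A <- dcenter(as.matrix(stats::dist(x)))
  B <- dcenter(as.matrix(stats::dist(y)))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

dcenter <- function(M) {
  rm <- rowMeans(M); gm <- mean(M)
  M - outer(rm, rep(1, ncol(M))) - outer(rep(1, nrow(M)), rm) + gm
}

#' k-nearest-neighbour mutual information (Kraskov type 1)
#'
#' Nonparametric MI in nats from max-norm k-nearest-neighbour distances in
#' the joint space: `psi(k) + psi(n) - mean(psi(nx + 1) + psi(ny + 1))`,
#' where `nx`, `ny` count marginal neighbours strictly within the joint kNN
#' radius. Ties are broken by an infinitesimal seeded jitter (scale 1e-10).
#' The estimate may be slightly negative for independent data.
#'
#' @param x,y numeric vectors of equal length `n > k_neighbors`.
#' @param k_neighbors neighbourhood size (default 3).
#' @param seed seed for the tie-breaking jitter.
#' @return MI estimate in nats.
#' @export
knn_mi <- function(x, y, k_neighbors = 3L, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- as.integer(k_neighbors)
  if (n <= k) stop("need more observations than k_neighbors", call. = FALSE)
  set.seed(child_seed(seed, 641L))
  x <- as.numeric(x); y <- as.numeric(y)
  # standardize the marginals: the max-norm neighbourhoods of the joint
  # space are meaningless when the two scales differ by orders of magnitude
  if (stats::sd(x) > 0) x <- (x - mean(x)) / stats::sd(x)
  if (stats::sd(y) > 0) y <- (y - mean(y)) / stats::sd(y)
  x <- x + stats::rnorm(n, 0, 1e-10)
  y <- y + stats::rnorm(n, 0, 1e-10)
  ox <- order(x); sx <- x[ox]
  oy <- order(y); sy <- y[oy]
  nx <- integer(n); ny <- integer(n)
  for (i in seq_len(n)) {
    dj <- pmax(abs(x - x[i]), abs(y - y[i]))
    eps <- sort(dj, partial = k + 1)[k + 1]   # joint kNN radius (self at 0)
    # strictly-within counts from the sorted marginals, minus self
    nx[i] <- count_within(sx, x[i], eps) - 1L
    ny[i] <- count_within(sy, y[i], eps) - 1L
  }
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

count_within <- function(sorted, center, eps) {
  hi <- findInterval(center + eps, sorted, left.open = TRUE)   # x_j < c + eps
  lo <- findInterval(center - eps, sorted)                     # x_j <= c - eps
  hi - lo
}

#' Rank genes by association with the recovered cycle
#'
#' Per gene: order the series by the consensus linearization, smooth it with
#' the random-walk-plus-noise RTS smoother ([fit_rwp()] + [rts_smooth()]),
#' then measure distance correlation and KNN mutual information between the
#' smoothed series and the ordinal time index `1..T`.
#'
#' By default the statistics are computed on the raw ordered series. The
#' smoothed alternative (`smooth = TRUE`) re-runs fit + smooth + statistic
#' on every permutation so observed and null remain exchangeable, but it is
#' kept off by default for a structural reason: both statistics are
#' invariant to the scale of their arguments, so the RTS smooth of a
#' pure-noise gene — a low-amplitude but perfectly smooth trend whenever
#' the variance fit escapes the boundary — scores as high as a genuine
#' oscillation, and no ranking of smoothed statistics can separate the two.
#' The raw series keeps amplitude in the statistic and ranks cleanly.
#'
#' With permutations, genes are ranked by p-value (ascending), ties broken
#' by the permutation z-score `(observed - mean(null)) / sd(null)` and then
#' gene id; without permutations the raw statistic ranks, descending.
#' Benjamini-Hochberg q-values are reported across genes.
#'
#' @param mat log2-layer [expr_matrix()] covering the order's cells (all
#'   genes, not only the cycle catalog).
#' @param order a `consensus_order`.
#' @param n_perm permutations for p-values (0 = statistics only, p missing).
#' @param seed master seed.
#' @param smooth RTS-smooth each series (and each permuted series) before
#'   testing; see above.
#' @param k_neighbors passed to [knn_mi()].
#' @return tibble of class `association_result`: `gene_id`, `dcor`,
#'   `dcor_p`, `dcor_q`, `dcor_z`, `mi`, `mi_p`, `mi_q`, `mi_z`, `rank`.
#' @export
rank_cycle_genes <- function(mat, order, n_perm = 0L, seed = 1L,
                             smooth = FALSE, k_neighbors = 3L) {
  stopifnot(inherits(mat, "expr_matrix"))
  ids <- order$cell_id[order(order$linear_rank)]
  miss <- setdiff(ids, cell_ids(mat))
  if (length(miss)) stop("order refers to cells absent from the matrix",
                         call. = FALSE)
  V <- mat$values[, ids, drop = FALSE]
  T_ <- ncol(V)
  tt <- seq_len(T_)
  perms <- if (n_perm > 0) {
    set.seed(child_seed(seed, 733L))
    lapply(seq_len(n_perm), function(i) sample.int(T_))
  } else list()
  stat_pair <- function(e, mi_seed) {
    z <- if (smooth && stats::var(e) > 0) {
      rts_smooth(fit_rwp(e), e)$smoothed
    } else e
    if (stats::var(z) == 0) return(c(dcor = 0, mi = 0))
    c(dcor = dcor(z, tt),
      mi = knn_mi(z, tt, k_neighbors, seed = mi_seed))
  }
  res <- purrr::map(seq_len(nrow(V)), function(g) {
    e <- V[g, ]
    obs <- stat_pair(e, child_seed(seed, 829L, g))
    if (n_perm > 0) {
      null <- vapply(seq_along(perms), function(i)
        stat_pair(e[perms[[i]]], child_seed(seed, 907L, i)), numeric(2))
      pz <- function(o, nn) {
        o <- unname(o)
        s <- stats::sd(nn)
        z <- if (is.finite(s) && s > 0) (o - mean(nn)) / s
             else if (o > max(nn)) Inf else 0
        c(p = (1 + sum(nn >= o)) / (n_perm + 1), z = z)
      }
      dcz <- pz(obs["dcor"], null["dcor", ])
      miz <- pz(obs["mi"], null["mi", ])
    } else {
      dcz <- miz <- c(p = NA_real_, z = NA_real_)
    }
    tibble::tibble(gene_id = rownames(V)[g],
                   dcor = unname(obs["dcor"]), dcor_p = unname(dcz["p"]),
                   dcor_z = unname(dcz["z"]),
                   mi = unname(obs["mi"]), mi_p = unname(miz["p"]),
                   mi_z = unname(miz["z"]))
  }) |> purrr::list_rbind()
  res <- res |>
    dplyr::mutate(dcor_q = stats::p.adjust(.data$dcor_p, "BH"),
                  mi_q = stats::p.adjust(.data$mi_p, "BH"))
  res <- if (n_perm > 0) {
    dplyr::arrange(res, .data$dcor_p, dplyr::desc(.data$dcor_z),
                   .data$gene_id)
  } else {
    dplyr::arrange(res, dplyr::desc(.data$dcor), .data$gene_id)
  }
  res <- res |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("gene_id", "dcor", "dcor_p", "dcor_q", "dcor_z",
                  "mi", "mi_p", "mi_q", "mi_z", "rank")
  class(res) <- c("association_result", class(res))
  res
}
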