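#' Consensus circular pseudotime
#'
#' The core ordering step: for each cluster number `k` in `k_min..k_max`, fit
#' a Gaussian mixture, find the shortest arbitrary-insertion tour over the
#' cluster means, and place every cell on the circle at its cluster's arc
#' (cells within a cluster spread uniformly over the arc, ordered by their
#' projection onto the direction from the previous to the next cluster mean).
#' The per-k circular position vectors are then aligned to the first usable k
#' by the optimal rotation/reflection (maximizing the resultant of unit
#' phasor differences) and merged by per-cell circular means into one
#' consensus position \eqn{\theta_i \in [0,1)}.
#'
#' @param mat log2-layer [expr_matrix()] restricted to cycle genes.
#' @param k_min,k_max cluster-number sweep; default `k_max` is
#'   `min(floor(n/10), 30)` (at least `k_min + 1`) so clusters average >= 10
#'   cells.
#' @param n_fold tour restart multiplier per k.
#' @param seed master seed; per-(k, restart) child seeds are derived by a
#'   fixed counter scheme.
#' @param n_init GMM restarts per k.
#' @return a `consensus_order` tibble: `cell_id`, `theta` in `[0,1)`,
#'   `linear_rank` (cut at theta = 0, ascending). Attribute `provenance`
#'   records the k values, tour lengths and seeds used.
#' @export
consensus_order <- function(mat, k_min = 7L, k_max = NULL, n_fold = 2L,
                            seed = 1L, n_init = 5L) {
  stopifnot(inherits(mat, "expr_matrix"))
  n <- ncol(mat$values)
  if (is.null(k_max)) k_max <- max(k_min + 1L, min(n %/% 10L, 30L))
  if (k_max > n) stop("k_max exceeds the number of cells", call. = FALSE)
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  pos <- list(); lens <- numeric(0); used <- integer(0)
  for (k in ks) {
    p <- tryCatch(
      single_k_positions(mat, k, n_fold = n_fold,
                         seed = child_seed(seed, 131L, k), n_init = n_init),
      error = function(e) {
        warning("skipping k=", k, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(p)) next
    pos[[length(pos) + 1L]] <- p$theta
    lens <- c(lens, p$tour$total_length)
    used <- c(used, k)
  }
  if (length(pos) < 2) stop("fewer than 2 usable k values in the sweep",
                            call. = FALSE)
  ref <- pos[[1]]
  aligned <- vapply(pos, align_circular, numeric(n), ref = ref)
  z <- rowSums(exp(2i * pi * aligned))
  theta <- (Arg(z) / (2 * pi)) %% 1
  out <- tibble::tibble(cell_id = cell_ids(mat), theta = theta) |>
    dplyr::mutate(linear_rank = rank(.data$theta, ties.method = "first"))
  attr(out, "provenance") <- list(k_values = used, tour_lengths = lens,
                                  seed = seed, n_fold = n_fold)
  class(out) <- c("consensus_order", class(out))
  out
}

# circular positions of all cells for one k: GMM + best tour + arc spreading
single_k_positions <- function(mat, k, n_fold, seed, n_init = 5L) {
  gm <- fit_gmm(mat, k, seed = child_seed(seed, 311L), n_init = n_init)
  assign <- max.col(gm$responsibilities, ties.method = "first")
  if (length(unique(assign)) < k) stop("degenerate GMM: empty cluster")
  D <- cluster_distance_matrix(gm)
  tour <- best_tour(D, k = k, n_fold = n_fold, seed = child_seed(seed, 577L))
  theta <- cell_arc_positions(t(mat$values), assign, gm$means, tour$node_order)
  list(theta = theta, tour = tour, gmm = gm)
}

# place cells on [0,1): cluster at tour position j owns arc [(j-1)/k, j/k);
# within the arc, cells are evenly spaced in the order of their projection
# onto (mu_next - mu_prev), i.e. the local direction of travel.
cell_arc_positions <- function(X, assign, means, node_order) {
  k <- length(node_order)
  n <- nrow(X)
  theta <- numeric(n)
  for (j in seq_len(k)) {
    cl <- node_order[j]
    idx <- which(assign == cl)
    m <- length(idx)
    if (m == 0) next
    prev <- node_order[if (j == 1) k else j - 1]
    nxt <- node_order[if (j == k) 1 else j + 1]
    dir <- means[nxt, ] - means[prev, ]
    proj <- as.numeric(X[idx, , drop = FALSE] %*% dir)
    ord <- rank(proj, ties.method = "first")
    theta[idx] <- (j - 1 + (ord - 0.5) / m) / k
  }
  theta
}

# align circular positions p to reference r by the rotation/reflection
# maximizing |sum exp(2*pi*i*(r - s*p))|; returns s*p + delta (mod 1)
align_circular <- function(p, ref) {
  z_fwd <- sum(exp(2i * pi * (ref - p)))
  z_rev <- sum(exp(2i * pi * (ref + p)))
  if (Mod(z_fwd) >= Mod(z_rev)) {
    (p + Arg(z_fwd) / (2 * pi)) %% 1
  } else {
    (-p + Arg(z_rev) / (2 * pi)) %% 1
  }
}

#' Circular order from a single cluster number
#'
#' The non-consensus baseline: one Gaussian mixture at the given `k`, one
#' best-of-restarts tour over its cluster means, and per-cell circular
#' positions from the cluster arcs. At `"cluster"` granularity every cell
#' sits at its cluster's arc midpoint (the classical cluster-index order,
#' `l_i = j`); `"cell"` granularity adds the within-arc projection
#' refinement the consensus merge uses.
#'
#' @inheritParams consensus_order
#' @param k the single cluster number.
#' @param granularity `"cluster"` (default) or `"cell"`.
#' @return a `consensus_order`-shaped tibble (`cell_id`, `theta`,
#'   `linear_rank`) with single-k provenance.
#' @export
single_k_order <- function(mat, k, n_fold = 2L, seed = 1L, n_init = 5L,
                           granularity = c("cluster", "cell")) {
  granularity <- match.arg(granularity)
  p <- single_k_positions(mat, k, n_fold = n_fold, seed = seed,
                          n_init = n_init)
  theta <- p$theta
  if (granularity == "cluster") {
    # collapse within-arc refinement to the arc midpoint
    theta <- (floor(theta * k) + 0.5) / k
  }
  out <- tibble::tibble(cell_id = cell_ids(mat), theta = theta) |>
    dplyr::mutate(linear_rank = rank(.data$theta, ties.method = "first"))
  attr(out, "provenance") <- list(k_values = k,
                                  tour_lengths = p$tour$total_length,
                                  seed = seed, n_fold = n_fold)
  class(out) <- c("consensus_order", class(out))
  out
}

#' Re-linearize a consensus order
#'
#' Cuts the circle at `cut` and optionally reverses direction; positions
#' (mod 1) are unchanged, only the linearization moves.
#'
#' @param order a `consensus_order`.
#' @param cut position in `[0,1)` at which to cut.
#' @param reverse traverse the circle in the opposite direction.
#' @return a `consensus_order` with updated `theta` origin and `linear_rank`.
#' @export
relinearize <- function(order, cut = 0, reverse = FALSE) {
  th <- (order$theta - cut) %% 1
  if (reverse) th <- (-th) %% 1
  out <- order
  out$theta <- th
  out$linear_rank <- rank(th, ties.method = "first")
  out
}

#' Circular correlation of two position vectors
#'
#' Fisher–Lee circular correlation between two sets of circular positions in
#' `[0,1)` (used to compare a recovered order with a known phase). Invariant
#' to rotation of either argument; reflection flips the sign.
#'
#' @param a,b numeric vectors of positions in `[0,1)`.
#' @return correlation in `[-1, 1]`.
#' @export
circ_cor <- function(a, b) {
  stopifnot(length(a) == length(b))
  al <- 2 * pi * a; be <- 2 * pi * b
  da <- outer(al, al, "-"); db <- outer(be, be, "-")
  num <- sum(sin(da) * sin(db))
  den <- sqrt(sum(sin(da)^2) * sum(sin(db)^2))
  if (den == 0) return(0)
  num / den
}

#' @export
print.consensus_order <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("<consensus_order> %d cells; k = %s; seed %s\n", nrow(x),
              paste(range(pr$k_values), collapse = ".."), pr$seed))
  NextMethod()
}
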