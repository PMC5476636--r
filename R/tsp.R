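#' Arbitrary-insertion tour construction
#'
#' Randomized O(k^2) heuristic for the Euclidean traveling-salesman cycle
#' over cluster means: start from a random edge, then repeatedly insert a
#' uniformly chosen unvisited node at the position of minimal length
#' increase (worst-case 2 ln(k) approximation). Ties in insertion cost break
#' toward the smallest insertion index. Deterministic given `seed`.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param seed integer seed.
#' @return object of class `tour_cycle`: `node_order` (circular permutation),
#'   `total_length`, `k`.
#' @export
arbitrary_insertion_tour <- function(D, seed = 1L) {
  D <- as.matrix(D)
  k <- nrow(D)
  stopifnot(ncol(D) == k)
  if (k < 1) stop("empty distance matrix", call. = FALSE)
  if (k < 3) {
    return(new_tour(seq_len(k), D))
  }
  set.seed(seed)
  start <- sample.int(k, 2L)
  rest <- sample(setdiff(seq_len(k), start))
  tour <- start
  for (v in rest) {
    len <- length(tour)
    a <- tour
    b <- tour[c(2:len, 1L)]
    delta <- D[a, v] + D[v, b] - D[cbind(a, b)]
    pos <- which.min(delta)          # first minimum = smallest insertion index
    tour <- append(tour, v, after = pos)
  }
  new_tour(tour, D)
}

new_tour <- function(order, D) {
  structure(list(node_order = as.integer(order),
                 total_length = tour_length(order, D),
                 k = length(order)),
            class = "tour_cycle")
}

#' Length of a closed tour
#' @param order node permutation.
#' @param D distance matrix.
#' @return sum of `D` along the cycle including the closing edge.
#' @export
tour_length <- function(order, D) {
  if (length(order) < 2) return(0)
  nxt <- order[c(2:length(order), 1L)]
  sum(D[cbind(order, nxt)])
}

#' @export
print.tour_cycle <- function(x, ...) {
  cat(sprintf("<tour_cycle> k=%d  length=%.4f  [%s]\n", x$k, x$total_length,
              paste(x$node_order, collapse = " ")))
  invisible(x)
}

#' Best-of-restarts tour
#'
#' Runs `n_fold * k` seeded arbitrary-insertion constructions and keeps the
#' shortest cycle. Restart seeds are a nested sequence of the master seed, so
#' the returned length is non-increasing in `n_fold`.
#'
#' @inheritParams arbitrary_insertion_tour
#' @param k number of nodes (defaults to `nrow(D)`); the restart budget is
#'   `n_fold * k`.
#' @param n_fold restart multiplier (>= 1).
#' @return the shortest `tour_cycle` found.
#' @export
best_tour <- function(D, k = nrow(as.matrix(D)), n_fold = 2L, seed = 1L) {
  stopifnot(n_fold >= 1)
  n_runs <- max(1L, as.integer(n_fold) * as.integer(k))
  best <- NULL
  for (i in seq_len(n_runs)) {
    t <- arbitrary_insertion_tour(D, seed = child_seed(seed, 977L, i))
    if (is.null(best) || t$total_length < best$total_length) best <- t
  }
  best
}
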