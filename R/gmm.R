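#' Gaussian mixture clustering of single cells
#'
#' Fits a k-component Gaussian mixture to cells (rows = cells, columns =
#' genes of the log2 layer) by EM, modelling log expression as approximately
#' Gaussian (lognormal approximation to negative-binomial counts). Means are
#' seeded by k-means; the best of `n_init` restarts by log-likelihood is
#' returned. Deterministic given `seed`.
#'
#' @param mat log2-layer [expr_matrix()].
#' @param k number of mixture components, `1 <= k <=` number of cells.
#' @param seed integer master seed.
#' @param n_init number of seeded restarts.
#' @param cov_type `"diagonal"` (default; variance floor 1e-6), `"spherical"`,
#'   or `"full"` (ridge-regularized).
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @return object of class `gmm_model`: `k`, `weights`, `means` (k x genes),
#'   `variances` (diagonal/spherical) or `covariances` (full),
#'   `responsibilities` (cells x k), `log_likelihood`, `ll_trace`, `cov_type`,
#'   `seed`.
#' @export
fit_gmm <- function(mat, k, seed = 1L, n_init = 10L,
                    cov_type = c("diagonal", "full", "spherical"),
                    max_iter = 200L, tol = 1e-8) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "log2") stop("fit_gmm expects the log2 layer", call. = FALSE)
  cov_type <- match.arg(cov_type)
  X <- t(mat$values)                      # cells x genes
  n <- nrow(X); m <- ncol(X)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")",
                  call. = FALSE)
  best <- NULL
  for (init in seq_len(max(1L, n_init))) {
    set.seed(child_seed(seed, 811L, init))
    fit <- tryCatch(gmm_em_once(X, k, cov_type, max_iter, tol),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$log_likelihood > best$log_likelihood)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all EM restarts failed", call. = FALSE)
  best$seed <- seed
  best$cell_ids <- rownames(X)
  best$gene_ids <- colnames(X)
  class(best) <- "gmm_model"
  best
}

# one EM run from a k-means seeding of the current RNG state
gmm_em_once <- function(X, k, cov_type, max_iter, tol) {
  n <- nrow(X); m <- ncol(X)
  floor_var <- 1e-6
  if (k == 1L) {
    assign <- rep(1L, n)
  } else if (k == n) {
    assign <- seq_len(n)
  } else {
    km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 1L,
                                         iter.max = 30L))
    assign <- km$cluster
  }
  R <- matrix(0, n, k); R[cbind(seq_len(n), assign)] <- 1
  w <- colMeans(R)
  mu <- m_step_means(X, R)
  vr <- m_step_vars(X, R, mu, cov_type, floor_var)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- component_logdens(X, mu, vr, cov_type)        # n x k
    logw <- sweep(logd, 2, log(pmax(w, 1e-300)), "+")
    mx <- apply(logw, 1, max)
    lse <- mx + log(rowSums(exp(logw - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    R <- exp(logw - lse)
    w <- colMeans(R)
    mu <- m_step_means(X, R)
    vr <- m_step_vars(X, R, mu, cov_type, floor_var)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  rownames(mu) <- paste0("c", seq_len(k))
  list(k = k, weights = w, means = mu, variances = vr,
       responsibilities = R, log_likelihood = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, cov_type = cov_type)
}

m_step_means <- function(X, R) {
  nk <- pmax(colSums(R), 1e-12)
  sweep(crossprod(R, X), 1, nk, "/")
}

m_step_vars <- function(X, R, mu, cov_type, floor_var) {
  k <- nrow(mu); m <- ncol(mu)
  nk <- pmax(colSums(R), 1e-12)
  if (cov_type == "full") {
    lapply(seq_len(k), function(r) {
      Xc <- sweep(X, 2, mu[r, ], "-")
      S <- crossprod(Xc * R[, r], Xc) / nk[r]
      S + diag(floor_var, m)
    })
  } else {
    V <- matrix(0, k, m)
    for (r in seq_len(k)) {
      Xc <- sweep(X, 2, mu[r, ], "-")
      V[r, ] <- colSums(Xc^2 * R[, r]) / nk[r]
    }
    if (cov_type == "spherical") V <- matrix(rowMeans(V), k, m)
    pmax(V, floor_var)
  }
}

component_logdens <- function(X, mu, vr, cov_type) {
  n <- nrow(X); k <- nrow(mu); m <- ncol(X)
  out <- matrix(0, n, k)
  if (cov_type == "full") {
    for (r in seq_len(k)) {
      ch <- chol(vr[[r]])
      Xc <- sweep(X, 2, mu[r, ], "-")
      z <- backsolve(ch, t(Xc), transpose = TRUE)
      out[, r] <- -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) +
                            colSums(z^2))
    }
  } else {
    for (r in seq_len(k)) {
      v <- vr[r, ]
      Xc <- sweep(X, 2, mu[r, ], "-")
      out[, r] <- -0.5 * (m * log(2 * pi) + sum(log(v)) +
                            colSums(t(Xc^2) / v))
    }
  }
  out
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> k=%d  cov=%s  logLik=%.3f  (%d EM iterations)\n",
              x$k, x$cov_type, x$log_likelihood, length(x$ll_trace)))
  invisible(x)
}

#' Hard cluster assignment
#'
#' Argmax responsibility per cell; ties broken toward the lowest cluster
#' index for deterministic downstream ordering.
#'
#' @param model a `gmm_model`.
#' @return tibble with `cell_id`, `cluster`.
#' @export
cluster_assignment <- function(model) {
  lab <- max.col(model$responsibilities, ties.method = "first")
  tibble::tibble(cell_id = model$cell_ids, cluster = lab)
}

#' Euclidean distances between cluster means
#'
#' @param model a `gmm_model`.
#' @return symmetric k x k matrix with zero diagonal; satisfies the triangle
#'   inequality (Euclidean), as the tour construction requires.
#' @export
cluster_distance_matrix <- function(model) {
  as.matrix(stats::dist(model$means))
}

#' @export
tidy.gmm_model <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    weight = x$weights,
    size = colSums(x$responsibilities))
}

#' @export
glance.gmm_model <- function(x, ...) {
  tibble::tibble(k = x$k, cov_type = x$cov_type,
                 log_likelihood = x$log_likelihood,
                 iterations = length(x$ll_trace))
}

#' Serialize a mixture model to JSON
#' @param model a `gmm_model` (diagonal or spherical covariance).
#' @param path output path.
#' @export
write_gmm_json <- function(model, path) {
  stopifnot(model$cov_type != "full")
  jsonlite::write_json(
    list(k = model$k, seed = model$seed, cov_type = model$cov_type,
         weights = model$weights, means = model$means,
         variances = model$variances, gene_ids = model$gene_ids),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

# deterministic child-seed scheme: master seed + a stream tag + a counter,
# folded into [0, 2^31). Used by every randomized stage.
child_seed <- function(seed, stream, counter = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 30269 +
                as.double(counter) * 97) %% 2147483647)
}
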