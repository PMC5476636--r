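#' Stage-segmentation hidden Markov model
#'
#' Left-to-right chain over the cell-cycle stages (optionally G0, then G1, S,
#' G2M) with multivariate-Gaussian emissions (diagonal covariance, floored)
#' over the 9-dimensional score vectors. Transitions are allowed only from a
#' stage to itself or to the physiologically subsequent stage; the chain is
#' open (the final stage is absorbing) because circularity is handled by the
#' start search ([find_start()]).
#'
#' @param track a [score_track()] (length >= 2 x number of states).
#' @param include_g0 include a G0 state before G1.
#' @param seed integer seed (initialization determinism).
#' @param max_iter,tol Baum-Welch stopping rule.
#' @return object of class `cycle_hmm`: `states`, `A` (transition matrix),
#'   `means` (states x 9), `variances` (states x 9), `log_likelihood`,
#'   `ll_trace`, `converged`.
#' @export
fit_hmm <- function(track, include_g0 = FALSE, seed = 1L, max_iter = 100L,
                    tol = 1e-6) {
  obs <- track_obs(track)
  states <- hmm_states(include_g0)
  N <- length(states)
  if (nrow(obs) < 2 * N) stop("track too short for ", N, " states", call. = FALSE)
  set.seed(child_seed(seed, 409L))
  init <- hmm_init_track(track, obs, include_g0)
  baum_welch(obs, init$means, init$vars, init$A, states, max_iter, tol)
}

# Emission initialization. For a score track the states are anchored to the
# score semantics (provisional stage = argmax Bayes-score; provisional G0 =
# depressed mean-scores), which makes the rotation search identifiable: the
# anchored init is rotation-invariant, so only the rotation whose block
# structure matches the anchors reaches the top likelihood. Bare matrices
# fall back to positional quantile slices.
hmm_init_track <- function(track, obs, include_g0) {
  N <- length(hmm_states(include_g0))
  fallback <- hmm_init(obs, N)
  if (!(is.data.frame(track) &&
        all(c("bayes_G1", "bayes_S", "bayes_G2M") %in% names(track)))) {
    return(fallback)
  }
  tr <- track[order(track$rank), , drop = FALSE]
  bayes <- as.matrix(tr[, c("bayes_G1", "bayes_S", "bayes_G2M")])
  prov <- max.col(bayes, ties.method = "first")        # 1=G1 2=S 3=G2M
  if (include_g0) {
    msum <- rowSums(as.matrix(tr[, c("mean_G1", "mean_G1S", "mean_S",
                                     "mean_G2", "mean_G2M", "mean_M")]))
    g0 <- msum < stats::quantile(msum, 0.15)
    prov <- ifelse(g0, 1L, prov + 1L)
  }
  means <- fallback$means; vars <- fallback$vars
  for (h in seq_len(N)) {
    idx <- which(prov == h)
    if (length(idx) >= 2) {
      means[h, ] <- colMeans(obs[idx, , drop = FALSE])
      v <- apply(obs[idx, , drop = FALSE], 2, stats::var)
      vars[h, ] <- pmax(ifelse(is.na(v), 1, v), 1e-6)
    }
  }
  list(means = means, vars = vars, A = fallback$A)
}

hmm_states <- function(include_g0) {
  if (include_g0) c("G0", "G1", "S", "G2M") else c("G1", "S", "G2M")
}

track_obs <- function(track) {
  if (inherits(track, "score_track") || is.data.frame(track)) {
    cols <- intersect(score_columns, names(track))
    as.matrix(track[order(track$rank), cols, drop = FALSE])
  } else {
    as.matrix(track)
  }
}

# quantile-slice initialization: contiguous positional blocks seed the state
# means/variances; left-to-right transitions start sticky (0.9 self).
hmm_init <- function(obs, N) {
  n <- nrow(obs)
  block <- pmin(N, 1L + ((seq_len(n) - 1L) * N) %/% n)
  means <- do.call(rbind, lapply(seq_len(N), function(h)
    colMeans(obs[block == h, , drop = FALSE])))
  vars <- do.call(rbind, lapply(seq_len(N), function(h) {
    v <- apply(obs[block == h, , drop = FALSE], 2, stats::var)
    pmax(ifelse(is.na(v), 1, v), 1e-6)
  }))
  A <- matrix(0, N, N)
  for (i in seq_len(N - 1)) { A[i, i] <- 0.9; A[i, i + 1] <- 0.1 }
  A[N, N] <- 1
  list(means = means, vars = vars, A = A)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

emission_logdens <- function(obs, means, vars) {
  n <- nrow(obs); N <- nrow(means)
  B <- matrix(0, n, N)
  for (h in seq_len(N)) {
    B[, h] <- -0.5 * (ncol(obs) * log(2 * pi) + sum(log(vars[h, ])) +
                        colSums((t(obs) - means[h, ])^2 / vars[h, ]))
  }
  B
}

hmm_forward <- function(logB, logA, lpi) {
  n <- nrow(logB); N <- ncol(logB)
  la <- matrix(-Inf, n, N)
  la[1, ] <- lpi + logB[1, ]
  for (t in 2:n) {
    for (h in seq_len(N)) {
      la[t, h] <- logsumexp(la[t - 1, ] + logA[, h]) + logB[t, h]
    }
  }
  la
}

hmm_backward <- function(logB, logA) {
  n <- nrow(logB); N <- ncol(logB)
  lb <- matrix(0, n, N)
  for (t in (n - 1):1) {
    for (h in seq_len(N)) {
      lb[t, h] <- logsumexp(logA[h, ] + logB[t + 1, ] + lb[t + 1, ])
    }
  }
  lb
}

baum_welch <- function(obs, means, vars, A, states, max_iter, tol) {
  n <- nrow(obs); N <- length(states)
  lpi <- c(0, rep(-Inf, N - 1))         # series starts in the first stage
  mask <- A > 0
  ll_trace <- numeric(0); ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    logA <- suppressWarnings(log(A)); logA[!mask] <- -Inf
    logB <- emission_logdens(obs, means, vars)
    la <- hmm_forward(logB, logA, lpi)
    lb <- hmm_backward(logB, logA)
    ll <- logsumexp(la[n, ])
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    gamma <- exp(la + lb - ll)
    # transition expected counts on the allowed structure
    for (i in seq_len(N)) {
      num <- rep(0, N)
      for (j in which(mask[i, ])) {
        num[j] <- sum(exp(la[-n, i] + logA[i, j] + logB[-1, j] + lb[-1, j] - ll))
      }
      if (sum(num) > 0) A[i, ] <- num / sum(num)
    }
    wk <- colSums(gamma)
    for (h in seq_len(N)) {
      if (wk[h] < 1e-8) next                     # starved state keeps params
      means[h, ] <- colSums(obs * gamma[, h]) / wk[h]
      vars[h, ] <- pmax(colSums((t(t(obs) - means[h, ]))^2 * gamma[, h]) / wk[h],
                        1e-6)
    }
  }
  if (!converged) warning("Baum-Welch did not converge in ", max_iter,
                          " iterations", call. = FALSE)
  rownames(means) <- rownames(vars) <- rownames(A) <- colnames(A) <- states
  structure(list(states = states, A = A, means = means, variances = vars,
                 log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, converged = converged),
            class = "cycle_hmm")
}

#' Assemble a stage HMM from explicit parameters
#'
#' Mostly for testing and for evaluating hand-set models; validates the
#' left-to-right transition structure.
#'
#' @param means,variances states x dims matrices.
#' @param A transition matrix (rows sum to 1; mass only on self/successor).
#' @param states state names in stage order.
#' @return a `cycle_hmm`.
#' @export
make_cycle_hmm <- function(means, variances, A, states = rownames(A)) {
  N <- length(states)
  stopifnot(nrow(A) == N, all(abs(rowSums(A) - 1) < 1e-8))
  off <- A; for (i in seq_len(N)) off[i, i:min(i + 1, N)] <- 0
  if (any(off != 0)) stop("transition mass outside self/successor entries",
                          call. = FALSE)
  structure(list(states = states, A = A, means = as.matrix(means),
                 variances = as.matrix(variances), log_likelihood = NA_real_,
                 ll_trace = numeric(0), converged = TRUE),
            class = "cycle_hmm")
}

#' @export
print.cycle_hmm <- function(x, ...) {
  cat(sprintf("<cycle_hmm> states: %s  logLik=%.3f  converged=%s\n",
              paste(x$states, collapse = " -> "), x$log_likelihood,
              x$converged))
  invisible(x)
}

#' @export
tidy.cycle_hmm <- function(x, ...) {
  tibble::as_tibble(x$means, rownames = "stage") |>
    tidyr::pivot_longer(-"stage", names_to = "score", values_to = "mean") |>
    dplyr::left_join(
      tibble::as_tibble(x$variances, rownames = "stage") |>
        tidyr::pivot_longer(-"stage", names_to = "score",
                            values_to = "variance"),
      by = c("stage", "score"))
}

#' @export
glance.cycle_hmm <- function(x, ...) {
  tibble::tibble(n_states = length(x$states),
                 log_likelihood = x$log_likelihood,
                 iterations = length(x$ll_trace), converged = x$converged)
}

#' Forward log-likelihood of a track under an HMM
#'
#' @param hmm a `cycle_hmm`.
#' @param track a [score_track()] or observation matrix.
#' @return total log-likelihood (natural log).
#' @export
hmm_loglik <- function(hmm, track) {
  obs <- track_obs(track)
  N <- length(hmm$states)
  logA <- suppressWarnings(log(hmm$A)); logA[hmm$A == 0] <- -Inf
  logB <- emission_logdens(obs, hmm$means, hmm$variances)
  la <- hmm_forward(logB, logA, c(0, rep(-Inf, N - 1)))
  logsumexp(la[nrow(obs), ])
}

# index map for a rotation/orientation of a circular series: position t of
# the transformed series takes original index idx[t]
circular_index <- function(n, rotation = 0L, orientation = 1L) {
  base <- seq_len(n)
  if (orientation == -1L) base <- rev(base)
  base[((seq_len(n) - 1L + rotation) %% n) + 1L]
}

#' Search the cycle start and orientation
#'
#' Tries every rotation of the circular track (and both traversal
#' directions) as the start of the linearized series and returns the
#' configuration with the highest HMM likelihood. By default the HMM is
#' refit per configuration; `refit = FALSE` fits once and only re-evaluates
#' likelihoods (much cheaper, same argmax in well-separated data).
#'
#' @inheritParams fit_hmm
#' @param refit refit the HMM for every rotation/orientation.
#' @return list: `rotation` (0-based), `orientation` (+1/-1), `likelihood`,
#'   `hmm` (the model fitted at the best configuration).
#' @export
find_start <- function(track, include_g0 = FALSE, seed = 1L, refit = TRUE,
                       max_iter = 50L) {
  obs <- track_obs(track)
  n <- nrow(obs)
  states <- hmm_states(include_g0)
  set.seed(child_seed(seed, 409L))
  init <- hmm_init_track(track, obs, include_g0)   # rotation-invariant anchor
  base_hmm <- if (!refit) {
    # scan with the anchored initial parameters; refit once at the winner
    make_cycle_hmm(init$means, init$vars, init$A, states)
  } else NULL
  best <- list(likelihood = -Inf)
  for (orientation in c(1L, -1L)) {
    for (rotation in 0:(n - 1)) {
      o <- obs[circular_index(n, rotation, orientation), , drop = FALSE]
      if (refit) {
        hm <- suppressWarnings(baum_welch(o, init$means, init$vars, init$A,
                                          states, max_iter, 1e-6))
        ll <- hm$log_likelihood
      } else {
        hm <- base_hmm
        ll <- hmm_loglik(base_hmm, o)
      }
      if (ll > best$likelihood) {
        best <- list(rotation = rotation, orientation = orientation,
                     likelihood = ll, hmm = hm)
      }
    }
  }
  if (!refit) {
    o <- obs[circular_index(n, best$rotation, best$orientation), , drop = FALSE]
    best$hmm <- suppressWarnings(baum_welch(o, init$means, init$vars, init$A,
                                            states, max_iter, 1e-6))
    best$likelihood <- best$hmm$log_likelihood
  }
  best
}

#' Most likely stage path (Viterbi)
#'
#' Decodes the max-probability state path under the left-to-right
#' transition structure; the path is non-decreasing in stage order by
#' construction.
#'
#' @param hmm a fitted `cycle_hmm`.
#' @param track a [score_track()].
#' @param rotation,orientation linearization of the circular track (e.g.
#'   from [find_start()]).
#' @return a `stage_path` tibble: `cell_id`, `rank` (position along the
#'   linearized series), `stage`. Attributes: `rotation`, `orientation`,
#'   `path_loglik`, `proportions`.
#' @export
viterbi_stages <- function(hmm, track, rotation = 0L, orientation = 1L) {
  obs <- track_obs(track)
  n <- nrow(obs)
  idx <- circular_index(n, rotation, orientation)
  o <- obs[idx, , drop = FALSE]
  N <- length(hmm$states)
  logA <- suppressWarnings(log(hmm$A)); logA[hmm$A == 0] <- -Inf
  logB <- emission_logdens(o, hmm$means, hmm$variances)
  delta <- matrix(-Inf, n, N); psi <- matrix(0L, n, N)
  delta[1, ] <- c(0, rep(-Inf, N - 1)) + logB[1, ]
  if (n > 1) for (t in 2:n) {
    for (h in seq_len(N)) {
      cand <- delta[t - 1, ] + logA[, h]
      psi[t, h] <- which.max(cand)
      delta[t, h] <- cand[psi[t, h]] + logB[t, h]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  ids <- if (is.data.frame(track)) track$cell_id[order(track$rank)][idx]
         else as.character(idx)
  out <- tibble::tibble(cell_id = ids, rank = seq_len(n),
                        stage = factor(hmm$states[path], levels = hmm$states))
  props <- prop.table(table(out$stage))
  attr(out, "rotation") <- rotation
  attr(out, "orientation") <- orientation
  attr(out, "path_loglik") <- max(delta[n, ])
  attr(out, "proportions") <- props
  class(out) <- c("stage_path", class(out))
  out
}

#' Per-group stage proportions
#'
#' @param path a `stage_path`.
#' @param groups optional per-cell group labels (named by cell id or aligned
#'   with the path); default one group.
#' @return tibble `group`, `stage`, `n`, `prop`; proportions sum to 1 within
#'   each group.
#' @export
stage_proportions <- function(path, groups = NULL) {
  if (is.null(groups)) {
    groups <- rep("all", nrow(path))
  } else {
    groups <- align_labels(groups, path$cell_id)
  }
  tibble::tibble(group = groups, stage = path$stage) |>
    dplyr::count(.data$group, .data$stage, .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
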