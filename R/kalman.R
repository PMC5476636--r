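#' Fit the random-walk-plus-noise model
#'
#' Scalar local-level state space for an ordered expression series:
#' observed `e_t = z_t + v`, latent `z_t = z_{t-1} + w`, with
#' `v ~ N(0, sigma_e^2)` and `w ~ N(0, sigma_z^2)`. Variances are estimated
#' by maximum likelihood (diffuse initial state; the first observation's
#' contribution is dropped) from a method-of-moments start on lagged
#' differences.
#'
#' The two boundary models are evaluated explicitly: pure observation noise
#' around a constant level (`sigma_z = 0`) and a pure random walk
#' (`sigma_e = 0`). The interior fit is kept only when it beats the better
#' boundary by a likelihood-ratio test at the boundary (5% level,
#' half-chi-squared(1)); otherwise the boundary model is adopted. This
#' parsimony rule makes the degenerate corners exactly reachable — a white
#' noise series smooths to its constant mean rather than to a spurious
#' low-amplitude trend, which is what keeps downstream association
#' statistics honest.
#'
#' @param e numeric series of length >= 3 (log2 layer).
#' @return object of class `rwp_model`: `sigma_e`, `sigma_z` (standard
#'   deviations), `loglik`, `degenerate` flag (constant input).
#' @export
fit_rwp <- function(e) {
  e <- as.numeric(e)
  T_ <- length(e)
  if (T_ < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(e) == 0) {
    return(structure(list(sigma_e = 0, sigma_z = 0, loglik = Inf,
                          degenerate = TRUE), class = "rwp_model"))
  }
  d <- diff(e)
  vd <- stats::var(d)
  g1 <- if (length(d) > 2) -stats::cov(d[-1], d[-length(d)]) else vd / 4
  s2e0 <- max(vd * 1e-3, min(g1, vd / 2))
  s2z0 <- max(vd * 1e-3, vd - 2 * s2e0)
  nll <- function(p) -rwp_loglik(e, exp(p[1]), exp(p[2]))
  lo <- log(stats::var(e)) - 18; hi <- log(stats::var(e)) + 6
  fit <- tryCatch(
    stats::optim(pmin(pmax(log(c(s2e0, s2z0)), lo), hi), nll,
                 method = "L-BFGS-B", lower = lo, upper = hi),
    error = function(err) NULL)
  # boundary models: constant level + noise, and noise-free random walk
  b_level <- stats::optimize(function(p) -rwp_loglik(e, exp(p), 0),
                             c(lo, hi))
  b_walk <- stats::optimize(function(p) -rwp_loglik(e, 0, exp(p)),
                            c(lo, hi))
  if (b_level$objective <= b_walk$objective) {
    bound <- list(s2e = exp(b_level$minimum), s2z = 0,
                  ll = -b_level$objective)
  } else {
    bound <- list(s2e = 0, s2z = exp(b_walk$minimum), ll = -b_walk$objective)
  }
  # keep the interior fit only if it clears the boundary LRT
  # (half-chi-squared(1) at 5%: 2*delta > qchisq(0.90, 1))
  if (!is.null(fit) && 2 * (-fit$value - bound$ll) > stats::qchisq(0.90, 1)) {
    s2e <- exp(fit$par[1]); s2z <- exp(fit$par[2]); ll <- -fit$value
  } else {
    s2e <- bound$s2e; s2z <- bound$s2z; ll <- bound$ll
  }
  structure(list(sigma_e = sqrt(s2e), sigma_z = sqrt(s2z), loglik = ll,
                 degenerate = FALSE), class = "rwp_model")
}

#' @export
print.rwp_model <- function(x, ...) {
  cat(sprintf("<rwp_model> sigma_e=%.4g sigma_z=%.4g logLik=%.3f\n",
              x$sigma_e, x$sigma_z, x$loglik))
  invisible(x)
}

#' @export
glance.rwp_model <- function(x, ...) {
  tibble::tibble(sigma_e = x$sigma_e, sigma_z = x$sigma_z, loglik = x$loglik,
                 degenerate = x$degenerate)
}

# forward Kalman filter for the local level model; diffuse start (posterior
# after e_1: mean e_1, variance s2e). Returns filtered moments + loglik.
rwp_filter <- function(e, s2e, s2z) {
  T_ <- length(e)
  a <- numeric(T_); P <- numeric(T_)
  a[1] <- e[1]; P[1] <- s2e
  ll <- 0
  if (T_ > 1) for (t in 2:T_) {
    R <- P[t - 1] + s2z            # predictive variance of z_t
    Fv <- R + s2e                  # predictive variance of e_t
    if (Fv <= 0) {                 # both variances zero: degenerate
      a[t] <- e[t]; P[t] <- 0
      next
    }
    ll <- ll + stats::dnorm(e[t], a[t - 1], sqrt(Fv), log = TRUE)
    K <- R / Fv
    a[t] <- a[t - 1] + K * (e[t] - a[t - 1])
    P[t] <- (1 - K) * R
  }
  list(a = a, P = P, loglik = ll)
}

rwp_loglik <- function(e, s2e, s2z) rwp_filter(e, s2e, s2z)$loglik

#' Rauch-Tung-Striebel smoothing of a series
#'
#' Forward Kalman filter followed by the backward RTS pass, returning the
#' smoothed latent expression and its variance at every index. Limits:
#' `sigma_e = 0` reproduces the observations exactly; `sigma_z = 0`
#' collapses to the series mean.
#'
#' @param model a fitted [fit_rwp()] model (or any list with `sigma_e`,
#'   `sigma_z`).
#' @param e the ordered series.
#' @param gene_id optional identifier carried into the output.
#' @return a `smoothed_series` tibble: `t`, `observed`, `smoothed`,
#'   `variance` (+ `gene_id` if given).
#' @export
rts_smooth <- function(model, e, gene_id = NULL) {
  e <- as.numeric(e)
  T_ <- length(e)
  s2e <- model$sigma_e^2; s2z <- model$sigma_z^2
  if (s2e == 0) {
    zhat <- e; V <- rep(0, T_)
  } else {
    f <- rwp_filter(e, s2e, s2z)
    zhat <- f$a; V <- f$P
    if (T_ > 1) for (t in (T_ - 1):1) {
      R <- f$P[t] + s2z
      C <- if (R > 0) f$P[t] / R else 0
      zhat[t] <- f$a[t] + C * (zhat[t + 1] - f$a[t])
      V[t] <- f$P[t] + C^2 * (V[t + 1] - R)
    }
  }
  out <- tibble::tibble(t = seq_len(T_), observed = e, smoothed = zhat,
                        variance = pmax(V, 0))
  if (!is.null(gene_id)) out$gene_id <- gene_id
  class(out) <- c("smoothed_series", class(out))
  out
}
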