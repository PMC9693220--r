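#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Classical EM for a `c`-component Gaussian mixture with full
#' covariances. Each restart is initialized with k-means++-style seeding
#' (first center uniform, subsequent centers with probability
#' proportional to the squared distance to the nearest chosen center);
#' the restart with the highest final log-likelihood is returned. A
#' singular covariance arising during the M-step is regularized with a
#' ridge of `1e-6 * trace/d` on the diagonal.
#'
#' @param x case table (`n x d` matrix or data frame).
#' @param n_components number of mixture components `c >= 1`.
#' @param seed optional integer; makes the fit reproducible without
#'   disturbing the caller's RNG state.
#' @param n_restarts independent EM runs (default 5).
#' @param tol convergence tolerance on the relative log-likelihood change
#'   between iterations (default `1e-6`).
#' @param max_iter iteration cap per run.
#' @return A [bayes_model()] with component labels `"1" ... "c"` ordered
#'   by the first feature of the component means. Attributes: `loglik`
#'   (final mixture log-likelihood), `loglik_trace` (per-iteration
#'   log-likelihoods of the winning run, nondecreasing), `n_iter`,
#'   `converged`.
#' @examples
#' x <- c(rnorm(200, 0), rnorm(200, 10))
#' fit <- fit_gmm_em(x, 2, seed = 1)
#' @export
fit_gmm_em <- function(x, n_components, seed = NULL, n_restarts = 5,
                       tol = 1e-6, max_iter = 500) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("case table contains non-finite values")
  n <- nrow(x)
  d <- ncol(x)
  c <- as.integer(n_components)
  if (c < 1L) stop("'n_components' must be >= 1")
  if (c > n) stop("more components (", c, ") than cases (", n, ")")
  run_seeded(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- em_single_run(x, c, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    em_as_model(best, d)
  })
}

em_single_run <- function(X, c, tol, max_iter) {
  n <- nrow(X)
  d <- ncol(X)
  mu <- kmeanspp_centers(X, c)
  S0 <- stats::cov(X) + diag(1e-6 * mean(diag(stats::cov(X))), d)
  if (c == 1L) {
    # closed form: one EM iteration lands on the sample moments
    mu <- matrix(colMeans(X), 1L, d)
    S <- stats::cov(X) * (n - 1) / n
    LW <- log_weighted_dens(X, list(S), mu, 1)
    return(list(w = 1, mu = mu, Sigma = list(S),
                loglik = sum(LW), trace = sum(LW), converged = TRUE))
  }
  Sigma <- rep(list(S0), c)
  w <- rep(1 / c, c)
  trace <- numeric(0L)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    LW <- log_weighted_dens(X, Sigma, mu, w)
    lev <- logsumexp_rows(LW)
    ll <- sum(lev)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && (ll - ll_prev) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    R <- exp(LW - lev)                      # responsibilities, n x c
    nk <- colSums(R)
    nk[nk < 1e-12] <- 1e-12                 # empty component guard
    w <- nk / n
    for (k in seq_len(c)) {
      mu[k, ] <- colSums(R[, k] * X) / nk[k]
      Xc <- sweep(X, 2L, mu[k, ])
      Sk <- crossprod(Xc * sqrt(R[, k])) / nk[k]
      Sigma[[k]] <- regularize_cov(Sk)
    }
  }
  list(w = w, mu = mu, Sigma = Sigma, loglik = trace[length(trace)],
       trace = trace, converged = converged)
}

kmeanspp_centers <- function(X, c) {
  n <- nrow(X)
  idx <- sample.int(n, 1L)
  centers <- X[idx, , drop = FALSE]
  while (nrow(centers) < c) {
    d2 <- apply(X, 1L, function(p) min(colSums((t(centers) - p)^2)))
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)          # degenerate duplicates; pick any
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers <- rbind(centers, X[idx, , drop = FALSE])
  }
  centers
}

log_weighted_dens <- function(X, Sigma, mu, w) {
  out <- vapply(seq_along(w), function(k) {
    R <- chol(Sigma[[k]])
    z <- backsolve(R, t(X) - mu[k, ], transpose = TRUE)
    log(w[k]) - 0.5 * colSums(z^2) - sum(log(diag(R))) -
      0.5 * ncol(X) * log(2 * pi)
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X))
}

regularize_cov <- function(S) {
  d <- nrow(S)
  ridge <- 1e-6 * sum(diag(S)) / d
  for (i in 0:6) {
    Sr <- S + diag(ridge * 10^i, d) * (i > 0)
    ok <- tryCatch({ chol(Sr); TRUE }, error = function(e) FALSE)
    if (ok && all(diag(Sr) > 0)) return(Sr)
  }
  S + diag(max(1e-8, ridge * 1e6), d)
}

em_as_model <- function(fit, d) {
  ord <- order(fit$mu[, 1L])
  comps <- lapply(seq_along(ord), function(i) {
    k <- ord[i]
    if (d == 1L) {
      gaussian_component(as.character(i), fit$mu[k, ],
                         sd = sqrt(fit$Sigma[[k]][1L, 1L]), weight = fit$w[k])
    } else {
      gaussian_component(as.character(i), fit$mu[k, ],
                         cov = fit$Sigma[[k]], weight = fit$w[k])
    }
  })
  model <- bayes_model(comps, normalize = TRUE)
  attr(model, "loglik") <- fit$loglik
  attr(model, "loglik_trace") <- fit$trace
  attr(model, "n_iter") <- length(fit$trace)
  attr(model, "converged") <- fit$converged
  model
}
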