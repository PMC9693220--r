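#' Gaussian class-conditional component
#'
#' One class of a closed-world Bayes model: a (multivariate) normal
#' likelihood `N(m, s)` together with the class prior probability
#' (its "weight"). Univariate components are parameterized by the
#' standard deviation `s`, multivariate ones by a symmetric
#' positive-definite covariance matrix.
#'
#' @param label class identifier (coerced to character).
#' @param mean numeric mean vector of length `d`, in the units of the
#'   measured feature (e.g. cm, ng/mL).
#' @param sd positive standard deviation; only for univariate components.
#' @param cov symmetric positive-definite `d x d` covariance matrix;
#'   required when `length(mean) > 1`. For `d = 1` a `1 x 1` matrix (or
#'   scalar variance) is accepted and converted to `sd`.
#' @param weight prior probability of the class, in `(0, 1]`.
#'
#' @return An object of class `gaussian_component`.
#' @examples
#' gaussian_component("girls", mean = 149.8081, sd = 0.5843, weight = 0.5)
#' @export
gaussian_component <- function(label, mean, sd = NULL, cov = NULL, weight = 1) {
  mean <- as.numeric(mean)
  d <- length(mean)
  if (d < 1L || anyNA(mean) || any(!is.finite(mean))) {
    stop("component mean must be a finite numeric vector")
  }
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0 || weight > 1) {
    stop("component weight must be a single number in (0, 1]")
  }
  if (is.null(sd) && is.null(cov)) stop("supply either 'sd' or 'cov'")
  if (!is.null(sd) && !is.null(cov)) stop("supply only one of 'sd' and 'cov'")
  if (!is.null(sd) && d > 1L) stop("'sd' is only valid for univariate components; use 'cov'")
  if (is.null(sd)) {
    cov <- as.matrix(cov)
    storage.mode(cov) <- "double"
    if (!all(dim(cov) == d)) stop("covariance must be ", d, " x ", d)
    if (anyNA(cov) || any(!is.finite(cov))) stop("covariance contains non-finite values")
    if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
      stop("covariance must be symmetric")
    }
    if (d == 1L) {
      sd <- sqrt(cov[1L, 1L])
      cov <- NULL
    }
  }
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != 1L || !is.finite(sd) || sd <= 0) {
      stop("'sd' must be a single positive number")
    }
  } else {
    # positive definiteness check: Cholesky must succeed
    ok <- tryCatch({ chol(cov); TRUE }, error = function(e) FALSE)
    if (!ok) stop("covariance matrix is not positive definite")
  }
  structure(
    list(label = as.character(label), mean = mean, sd = sd, cov = cov,
         weight = weight, d = d),
    class = "gaussian_component"
  )
}

#' @export
print.gaussian_component <- function(x, ...) {
  cat("<gaussian_component> label:", x$label, " d:", x$d,
      " weight:", format(x$weight), "\n")
  if (x$d == 1L) {
    cat("  mean:", format(x$mean), " sd:", format(x$sd), "\n")
  } else {
    cat("  mean:", paste(format(x$mean), collapse = ", "), "\n")
  }
  invisible(x)
}

# Covariance as a matrix regardless of the univariate/multivariate storage.
component_cov <- function(component) {
  if (!is.null(component$sd)) matrix(component$sd^2, 1L, 1L) else component$cov
}

#' Closed-world Bayes model
#'
#' An ordered set of [gaussian_component()] objects whose weights (class
#' priors) sum to one: under the closed-world assumption the components
#' are exhaustive, and their weighted likelihood sum at a point is the
#' evidence, the overall probability density of observing that value.
#'
#' @param components a list of [gaussian_component()] objects sharing the
#'   same dimension, with unique labels.
#' @param normalize if `TRUE`, rescale the component weights to sum to 1
#'   instead of requiring it.
#'
#' @return An object of class `bayes_model` with elements `components`,
#'   `d` (dimension) and `labels`.
#' @examples
#' m <- bayes_model(list(
#'   gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
#'   gaussian_component("boys", 151.0295, sd = 0.5108, weight = 0.5)
#' ))
#' @export
bayes_model <- function(components, normalize = FALSE) {
  if (inherits(components, "gaussian_component")) components <- list(components)
  if (!length(components) ||
      !all(vapply(components, inherits, logical(1L), "gaussian_component"))) {
    stop("'components' must be a non-empty list of gaussian_component objects")
  }
  d <- components[[1L]]$d
  if (!all(vapply(components, function(k) k$d, integer(1L)) == d)) {
    stop("all components must share the same dimension")
  }
  labels <- vapply(components, function(k) k$label, character(1L))
  if (anyDuplicated(labels)) stop("component labels must be unique")
  w <- vapply(components, function(k) k$weight, numeric(1L))
  if (normalize) {
    w <- w / sum(w)
    components <- Map(function(k, wi) { k$weight <- wi; k }, components, w)
  } else if (abs(sum(w) - 1) > 1e-9) {
    stop("component weights must sum to 1 (got ", format(sum(w)),
         "); use normalize = TRUE to rescale")
  }
  structure(list(components = components, d = d, labels = labels),
            class = "bayes_model")
}

#' @export
print.bayes_model <- function(x, ...) {
  cat("<bayes_model> d =", x$d, ",", length(x$components), "component(s)\n")
  for (k in x$components) {
    if (x$d == 1L) {
      cat(sprintf("  %-12s N(%s, %s)  weight %s\n", k$label,
                  format(k$mean), format(k$sd), format(k$weight)))
    } else {
      cat(sprintf("  %-12s mean (%s)  weight %s\n", k$label,
                  paste(format(k$mean), collapse = ", "), format(k$weight)))
    }
  }
  invisible(x)
}

model_weights <- function(model) {
  vapply(model$components, function(k) k$weight, numeric(1L))
}

model_means <- function(model) {
  do.call(rbind, lapply(model$components, function(k) k$mean))
}

#' Gaussian likelihood density
#'
#' Evaluates the (multivariate) normal density of one class component at
#' one or more points. This is the "likelihood function" of the class.
#'
#' @param component a [gaussian_component()].
#' @param x numeric vector (univariate cases) or `n x d` matrix.
#' @param log if `TRUE`, return the log density.
#' @return numeric vector of densities, one per case; strictly positive
#'   for finite `x` (up to floating-point underflow of `exp`).
#' @examples
#' gaussian_pdf(gaussian_component("z", 0, sd = 1), 0)  # 1/sqrt(2*pi)
#' @export
gaussian_pdf <- function(component, x, log = FALSE) {
  stopifnot(inherits(component, "gaussian_component"))
  X <- as_cases(x, component$d)
  lp <- component_log_pdf(component, X)
  if (log) lp else exp(lp)
}

# Log density evaluated directly from the closed form (univariate) or via
# the Cholesky factor (multivariate); keeps everything in log space so the
# evidence can be assembled with log-sum-exp.
component_log_pdf <- function(component, X) {
  d <- component$d
  if (d == 1L) {
    z <- (X[, 1L] - component$mean) / component$sd
    -0.5 * z^2 - log(component$sd) - 0.5 * log(2 * pi)
  } else {
    R <- chol(component$cov)
    z <- backsolve(R, t(X) - component$mean, transpose = TRUE)
    -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
  }
}

# n x c matrix of log(weight_k) + log pdf_k(x_i)
model_log_weighted <- function(model, X) {
  out <- vapply(model$components,
                function(k) log(k$weight) + component_log_pdf(k, X),
                numeric(nrow(X)))
  matrix(out, nrow = nrow(X), ncol = length(model$components),
         dimnames = list(NULL, model$labels))
}

#' Evidence of observations under a Bayes model
#'
#' The evidence is the denominator of Bayes' theorem: the prior-weighted
#' sum of the class likelihoods, i.e. the overall probability density of
#' observing a value under the closed-world model.
#'
#' @param model a [bayes_model()].
#' @param x cases: numeric vector or `n x d` matrix/data frame.
#' @return numeric vector of evidences, one per case.
#' @export
evidence <- function(model, x) {
  stopifnot(inherits(model, "bayes_model"))
  X <- as_cases(x, model$d)
  exp(logsumexp_rows(model_log_weighted(model, X)))
}

#' Posterior table: likelihoods, evidence and posteriors per case
#'
#' Applies Bayes' theorem `p(class | x) = p(class) * likelihood(x) /
#' evidence(x)` to every case. Computation is carried out in log space
#' with a log-sum-exp evidence so that posteriors stay defined far into
#' the distribution tails; a case only becomes undefined (`NA` posteriors,
#' `underflow` flag) when every class log density underflows to `-Inf`.
#'
#' @inheritParams evidence
#' @return An object of class `posterior_table`: a list with matrices
#'   `likelihoods` (`n x c` class densities) and `posteriors` (`n x c`,
#'   rows summing to 1), the numeric vector `evidence`, a logical vector
#'   `underflow` flagging undefined cases, and `labels`.
#' @export
posterior_table <- function(model, x) {
  stopifnot(inherits(model, "bayes_model"))
  X <- as_cases(x, model$d)
  LW <- model_log_weighted(model, X)
  lev <- logsumexp_rows(LW)
  post <- exp(LW - lev)
  underflow <- !is.finite(lev)
  post[underflow, ] <- NA_real_
  w <- model_weights(model)
  lik <- exp(sweep(LW, 2L, log(w), "-"))
  structure(
    list(likelihoods = lik, evidence = exp(lev), posteriors = post,
         underflow = underflow, labels = model$labels),
    class = "posterior_table"
  )
}

#' @export
print.posterior_table <- function(x, ...) {
  cat("<posterior_table>", nrow(x$posteriors), "case(s),",
      length(x$labels), "class(es)\n")
  print(utils::head(cbind(evidence = x$evidence, x$posteriors)))
  if (nrow(x$posteriors) > 6L) cat("  ...\n")
  invisible(x)
}

#' Fit a Bayes model from labeled groups
#'
#' Per-class sample means and sample standard deviations (univariate) or
#' covariances (multivariate) from a labeled case table. Class priors are
#' either equal (`1/c`, the default) or the observed class frequencies.
#' Equal priors are the default because unequal group sizes otherwise move
#' the decision boundaries away from the likelihood crossings.
#'
#' @param x case table (`n x d` matrix or data frame).
#' @param labels class label per case; `NA` labels are not allowed.
#' @param prior_mode `"equal"` or `"proportional"`.
#' @return A [bayes_model()] whose classes are the sorted unique labels.
#' @export
fit_from_labeled <- function(x, labels, prior_mode = c("equal", "proportional")) {
  prior_mode <- match.arg(prior_mode)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("'labels' must have one entry per case")
  if (anyNA(labels)) stop("unknown (NA) label in 'labels'")
  if (anyNA(x) || any(!is.finite(x))) stop("case table contains non-finite values")
  classes <- sort(unique(labels))
  n <- nrow(x)
  d <- ncol(x)
  comps <- lapply(classes, function(cl) {
    Xk <- x[labels == cl, , drop = FALSE]
    nk <- nrow(Xk)
    if (nk < 2L) stop("class '", cl, "' has fewer than 2 cases")
    w <- if (prior_mode == "equal") 1 / length(classes) else nk / n
    if (d == 1L) {
      s <- stats::sd(Xk[, 1L])
      if (s <= 0) stop("class '", cl, "' has zero variance")
      gaussian_component(cl, mean(Xk[, 1L]), sd = s, weight = w)
    } else {
      S <- stats::cov(Xk)
      if (any(diag(S) <= 0)) stop("class '", cl, "' has zero variance in a feature")
      gaussian_component(cl, colMeans(Xk), cov = S, weight = w)
    }
  })
  bayes_model(comps)
}
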