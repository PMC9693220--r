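#' Plain Bayes classification (maximum posterior)
#'
#' Assigns every case to the class with the largest posterior
#' probability. Ties are broken deterministically in favor of the
#' component with the lowest index.
#'
#' @inheritParams evidence
#' @return character vector of class labels, one per case.
#' @examples
#' m <- bayes_model(list(
#'   gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
#'   gaussian_component("boys", 151.0295, sd = 0.5108, weight = 0.5)
#' ))
#' bayes_classify(m, c(148, 155, 165))
#' @export
bayes_classify <- function(model, x) {
  stopifnot(inherits(model, "bayes_model"))
  X <- as_cases(x, model$d)
  LW <- model_log_weighted(model, X)
  model$labels[max.col(LW, ties.method = "first")]
}

#' One-dimensional Bayesian decision boundaries
#'
#' Finds every feature value where the prior-weighted likelihoods of a
#' pair of classes cross, i.e. where the maximum-posterior decision can
#' flip. A sign scan over an equidistant grid brackets the crossings and
#' each bracket is refined by root finding to within `1e-8` feature
#' units; boundaries closer than `1e-4` are de-duplicated. With unequal
#' variances a pair of Gaussians generically crosses twice, which is the
#' geometry behind implausible tail assignments.
#'
#' @param model a univariate [bayes_model()].
#' @param search_range numeric length-2 interval to scan. Default: the
#'   span of the component means widened by 5 times the largest
#'   component standard deviation.
#' @param resolution number of grid points for the sign scan.
#' @return A data frame of class `decision_boundaries` with columns
#'   `boundary` (sorted increasing), `class_a`, `class_b` (the pair of
#'   labels whose weighted likelihoods cross there). Zero rows when no
#'   crossing lies inside the range.
#' @examples
#' m <- bayes_model(list(
#'   gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
#'   gaussian_component("boys", 151.0295, sd = 0.5108, weight = 0.5)
#' ))
#' decision_boundaries_1d(m, c(140, 170))  # 150.43 and 159.55
#' @export
decision_boundaries_1d <- function(model, search_range = NULL, resolution = 4000) {
  stopifnot(inherits(model, "bayes_model"))
  if (model$d != 1L) stop("decision boundaries are computed for univariate models only")
  comps <- model$components
  if (is.null(search_range)) {
    mu <- vapply(comps, function(k) k$mean, numeric(1L))
    smax <- max(vapply(comps, function(k) k$sd, numeric(1L)))
    search_range <- c(min(mu) - 5 * smax, max(mu) + 5 * smax)
  }
  search_range <- sort(as.numeric(search_range))
  if (length(search_range) != 2L || any(!is.finite(search_range))) {
    stop("'search_range' must be a finite interval")
  }
  grid <- seq(search_range[1L], search_range[2L], length.out = resolution)
  Xg <- matrix(grid, ncol = 1L)
  LW <- model_log_weighted(model, Xg)
  out <- list()
  cidx <- utils::combn(length(comps), 2L)
  for (p in seq_len(ncol(cidx))) {
    i <- cidx[1L, p]; j <- cidx[2L, p]
    difffun <- function(x) {
      Xi <- matrix(x, ncol = 1L)
      (log(comps[[i]]$weight) + component_log_pdf(comps[[i]], Xi)) -
        (log(comps[[j]]$weight) + component_log_pdf(comps[[j]], Xi))
    }
    g <- LW[, i] - LW[, j]
    flips <- which(g[-1L] * g[-length(g)] < 0)
    roots <- vapply(flips, function(k) {
      stats::uniroot(difffun, c(grid[k], grid[k + 1L]), tol = 1e-10)$root
    }, numeric(1L))
    exact <- grid[g == 0]
    roots <- c(roots, exact)
    for (r in roots) {
      out[[length(out) + 1L]] <- data.frame(
        boundary = r, class_a = comps[[i]]$label, class_b = comps[[j]]$label,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(boundary = numeric(0L), class_a = character(0L),
                      class_b = character(0L), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$boundary), , drop = FALSE]
    keep <- c(TRUE, diff(res$boundary) > 1e-4)
    res <- res[keep, , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("decision_boundaries", "data.frame")
  res
}

#' @export
print.decision_boundaries <- function(x, ...) {
  cat("<decision_boundaries>", nrow(x), "boundary/ies\n")
  print.data.frame(x, ...)
  invisible(x)
}
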