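#' Computed ABC curve of positive values
#'
#' Sorts the values in decreasing order and accumulates their shares:
#' after the `i` largest items the *effort* is `i/n` (fraction of items
#' spent) and the *yield* is their cumulative share of the total. The
#' resulting effort/yield curve is nondecreasing, concave, ends at
#' (1, 1), and is invariant to rescaling the values by a positive
#' constant — the Pareto-type "important few vs. trivial many" picture.
#'
#' @param values positive finite numeric vector, `n >= 2`; input order is
#'   irrelevant.
#' @return An object of class `abc_curve`: list with `values` (sorted
#'   decreasing), `effort`, `yield`, `n`.
#' @examples
#' abc_curve(c(4, 3, 2, 1))$yield  # 0.4 0.7 0.9 1.0
#' @export
abc_curve <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("ABC analysis needs at least 2 values")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  if (any(values <= 0)) stop("ABC analysis is defined for strictly positive values")
  s <- sort(values, decreasing = TRUE)
  n <- length(s)
  structure(
    list(values = s, effort = seq_len(n) / n, yield = cumsum(s) / sum(s), n = n),
    class = "abc_curve"
  )
}

#' @export
print.abc_curve <- function(x, ...) {
  cat("<abc_curve>", x$n, "values; yield at effort 0.25/0.50/0.75:",
      paste(format(stats::approx(x$effort, x$yield, c(.25, .5, .75))$y,
                   digits = 3), collapse = "/"), "\n")
  invisible(x)
}

#' @export
as.data.frame.abc_curve <- function(x, ...) {
  data.frame(effort = x$effort, yield = x$yield, value = x$values)
}

#' ABC set limits and the low-evidence threshold
#'
#' Partitions the sorted values into the sets A ("important few"), B
#' (break-even) and C ("trivial many"). The B|C limit is the break-even
#' point: the last item whose per-item share of the total still matches
#' the per-item effort, i.e. whose value is at least the mean of all
#' values (unit slope of the piecewise-linear yield curve). The
#' threshold `epsilon` is the first value past break-even — the largest
#' member of set C — so that a strict comparison `value < epsilon` flags
#' exactly the items below it. The A|B limit is the curve point closest
#' to the ideal point (0, 1) (the Pareto point); it is reported for
#' completeness but plays no role in the classifier. When the Pareto
#' point falls beyond the break-even point (possible for weakly skewed
#' data) the A|B index is clamped to the B|C index so that the A, B, C
#' partition stays ordered; the unconstrained index is kept in
#' `pareto_index` and `exchanged` is set.
#'
#' @param curve an [abc_curve()].
#' @return An object of class `abc_limits`: list with `ab_index`,
#'   `bc_index`, `pareto_index`, `exchanged`, `epsilon`, and the index
#'   ranges `A`, `B`, `C`. With all values equal, C is empty and
#'   `epsilon` is the common value (nothing is strictly below it).
#' @examples
#' abc_limits(abc_curve(c(4, 3, 2, 1)))$epsilon  # 2
#' @export
abc_limits <- function(curve) {
  stopifnot(inherits(curve, "abc_curve"))
  v <- curve$values
  n <- curve$n
  pareto <- which.min(curve$effort^2 + (1 - curve$yield)^2)
  bc <- max(which(v >= mean(v)))
  ab <- min(pareto, bc)
  epsilon <- if (bc < n) v[bc + 1L] else min(v)
  structure(
    list(ab_index = ab, bc_index = bc, pareto_index = pareto,
         exchanged = pareto > bc, epsilon = epsilon,
         A = seq_len(ab),
         B = if (bc > ab) (ab + 1L):bc else integer(0L),
         C = if (bc < n) (bc + 1L):n else integer(0L)),
    class = "abc_limits"
  )
}

#' @export
print.abc_limits <- function(x, ...) {
  cat("<abc_limits> |A| =", length(x$A), " |B| =", length(x$B),
      " |C| =", length(x$C), " epsilon =", format(x$epsilon), "\n")
  invisible(x)
}

#' Low-evidence threshold from evidence values
#'
#' The minimum evidence required to trust a Bayes decision. Either the
#' B|C limit of a computed ABC analysis of the evidence values (the
#' default, a data-driven Pareto-type cutoff), or a fixed fraction of
#' the maximum evidence (1% by default). For a normal distribution the
#' ABC threshold captures approximately the range `m +/- 2s` and the 1%
#' rule the range `m +/- 3s`.
#'
#' @param evidences positive evidence values, either empirical (the
#'   cases being classified) or from an equidistant grid such as
#'   [evidence_grid()].
#' @param method `"abc"` or `"fraction"`.
#' @param fraction fraction of the maximum evidence for
#'   `method = "fraction"`, in (0, 1).
#' @return The threshold `epsilon` (scalar). Scales linearly with the
#'   evidence values for both methods.
#' @examples
#' compute_epsilon(c(4, 3, 2, 1), method = "abc")        # 2
#' compute_epsilon(c(0.4, 0.1), method = "fraction")     # 0.004
#' @export
compute_epsilon <- function(evidences, method = c("abc", "fraction"),
                            fraction = 0.01) {
  method <- match.arg(method)
  evidences <- as.numeric(evidences)
  if (!length(evidences)) stop("no evidence values supplied")
  if (anyNA(evidences) || any(!is.finite(evidences)) || any(evidences <= 0)) {
    stop("evidence values must be positive and finite")
  }
  if (method == "fraction") {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction >= 1) {
      stop("'fraction' must be in (0, 1)")
    }
    return(fraction * max(evidences))
  }
  abc_limits(abc_curve(evidences))$epsilon
}

#' Evidence on an equidistant grid
#'
#' Evaluates the model evidence at `n` equidistant supporting points of a
#' univariate range, the grid variant of the threshold input used e.g.
#' for calibration against known distributions.
#'
#' @param model a univariate [bayes_model()].
#' @param search_range numeric length-2 interval; defaults as in
#'   [decision_boundaries_1d()].
#' @param n number of grid points.
#' @return list with `x` (grid) and `evidence`.
#' @export
evidence_grid <- function(model, search_range = NULL, n = 1000) {
  stopifnot(inherits(model, "bayes_model"))
  if (model$d != 1L) {
    stop("grid evidence is univariate; use empirical evidences for d > 1")
  }
  if (is.null(search_range)) {
    mu <- vapply(model$components, function(k) k$mean, numeric(1L))
    smax <- max(vapply(model$components, function(k) k$sd, numeric(1L)))
    search_range <- c(min(mu) - 5 * smax, max(mu) + 5 * smax)
  }
  x <- seq(search_range[1L], search_range[2L], length.out = n)
  list(x = x, evidence = evidence(model, x))
}
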