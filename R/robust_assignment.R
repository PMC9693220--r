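#' Reasonable Bayes: suspend decisions below the evidence threshold
#'
#' Plain maximum-posterior classification with a reject option: a Bayes
#' decision is accepted only where there is sufficient evidence for the
#' observation. Cases whose evidence falls strictly below `epsilon` get
#' the uncertain sentinel `NA` instead of a forced class label; all other
#' cases keep their Bayes label.
#'
#' @inheritParams evidence
#' @param epsilon evidence threshold; if `NULL` it is computed from the
#'   empirical evidences of `x` via [compute_epsilon()].
#' @param epsilon_method,fraction passed to [compute_epsilon()] when
#'   `epsilon` is `NULL`.
#' @return An object of class `classification_result`: a data frame with
#'   columns `case`, `evidence`, one `posterior.<label>` column per
#'   class, `bayes` and `reasonable` (`NA` = uncertain). Attributes
#'   carry `epsilon`, `epsilon_method`, the `model` and the case matrix.
#' @examples
#' m <- bayes_model(list(
#'   gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
#'   gaussian_component("boys", 151.0295, sd = 0.5108, weight = 0.5)
#' ))
#' r <- reasonable_bayes(m, c(150, 151, 170), epsilon = 1e-4)
#' r$reasonable  # the 170 cm case is uncertain
#' @export
reasonable_bayes <- function(model, x, epsilon = NULL,
                             epsilon_method = c("abc", "fraction"),
                             fraction = 0.01) {
  stopifnot(inherits(model, "bayes_model"))
  epsilon_method <- match.arg(epsilon_method)
  X <- as_cases(x, model$d)
  pt <- posterior_table(model, X)
  if (is.null(epsilon)) {
    epsilon <- compute_epsilon(pt$evidence, method = epsilon_method,
                               fraction = fraction)
  } else {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
      stop("'epsilon' must be a single nonnegative number")
    }
    epsilon_method <- "fixed"
  }
  bayes <- model$labels[max.col(
    replace(log(pt$posteriors), is.na(pt$posteriors), -Inf),
    ties.method = "first")]
  bayes[pt$underflow] <- NA_character_
  uncertain <- pt$evidence < epsilon | pt$underflow
  reasonable <- ifelse(uncertain, NA_character_, bayes)
  post <- as.data.frame(pt$posteriors)
  names(post) <- paste0("posterior.", model$labels)
  out <- data.frame(case = seq_len(nrow(X)), evidence = pt$evidence,
                    post, bayes = bayes, reasonable = reasonable,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("classification_result", "data.frame"),
            epsilon = epsilon, epsilon_method = epsilon_method,
            model = model, cases = X)
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>", nrow(x), "case(s), epsilon =",
      format(attr(x, "epsilon")), paste0("(", attr(x, "epsilon_method"), ")"),
      "\n  uncertain:", sum(is.na(x$reasonable)), "case(s)")
  if (!is.null(x$plausible)) cat("; plausible labels present")
  cat("\n")
  print.data.frame(utils::head(x), digits = 4)
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Class centers (Voronoi cell generators)
#'
#' The center point of each class is the expected value of its
#' likelihood — the component mean. These centers generate the Voronoi
#' tessellation used by plausible Bayes: a point belongs to the cell of
#' the center it is closest to under the configured metric.
#'
#' @param model a [bayes_model()].
#' @param metric `"euclidean"` (raw feature units, default) or
#'   `"zscore"` (per-feature standardization applied at assignment time).
#' @return An object of class `class_centers`: list with `centers`
#'   (`c x d` matrix, rows named by class label), `labels`, `metric`.
#' @export
class_centers <- function(model, metric = c("euclidean", "zscore")) {
  stopifnot(inherits(model, "bayes_model"))
  metric <- match.arg(metric)
  centers <- model_means(model)
  rownames(centers) <- model$labels
  dup <- stats::dist(centers)
  if (any(dup < .Machine$double.eps^0.5)) {
    stop("duplicate class centers: Voronoi cells are ill-defined")
  }
  structure(list(centers = centers, labels = model$labels, metric = metric),
            class = "class_centers")
}

#' @export
print.class_centers <- function(x, ...) {
  cat("<class_centers>", nrow(x$centers), "center(s), metric:", x$metric, "\n")
  print(x$centers)
  invisible(x)
}

#' Plausible Bayes: relabel uncertain cases by nearest class center
#'
#' Every case left uncertain by [reasonable_bayes()] is assigned to the
#' class whose center is nearest: `class(x) = argmin_k d(x, m_k)`. For
#' point queries this is exactly membership in the Voronoi cell of the
#' winning center, for any dimension, without constructing the
#' tessellation. Certain cases keep their labels; exact distance ties go
#' to the lowest class index. The operation is idempotent.
#'
#' @param result a `classification_result` from [reasonable_bayes()].
#' @param centers a [class_centers()] object; default: the centers of
#'   the model stored in `result`.
#' @return `result` with a `plausible` column (never `NA`).
#' @export
plausible_bayes <- function(result, centers = NULL) {
  stopifnot(inherits(result, "classification_result"))
  if (is.null(centers)) centers <- class_centers(attr(result, "model"))
  stopifnot(inherits(centers, "class_centers"))
  X <- attr(result, "cases")
  if (ncol(X) != ncol(centers$centers)) {
    stop("centers and cases disagree in dimension")
  }
  base <- if (is.null(result$plausible)) result$reasonable else result$plausible
  todo <- which(is.na(base))
  if (length(todo)) {
    C <- centers$centers
    Xq <- X[todo, , drop = FALSE]
    if (centers$metric == "zscore") {
      s <- apply(X, 2L, stats::sd)
      s[s == 0 | !is.finite(s)] <- 1
      Xq <- sweep(Xq, 2L, s, "/")
      C <- sweep(C, 2L, s, "/")
    }
    # squared Euclidean distances, n_todo x c
    d2 <- outer(rowSums(Xq^2), rowSums(C^2), "+") - 2 * Xq %*% t(C)
    base[todo] <- centers$labels[max.col(-d2, ties.method = "first")]
  }
  result$plausible <- base
  result
}
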