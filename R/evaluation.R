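#' Accuracy and confusion counts
#'
#' Fraction of correctly labeled cases. Cases with missing truth are
#' always excluded. Uncertain predictions (`NA`) count as incorrect
#' unless `exclude_uncertain = TRUE`, in which case they are dropped
#' from the denominator and reported separately — the "classified-only"
#' accuracy of a classifier with a reject option. When nothing remains
#' to evaluate, the accuracy is an explicit `NA`, not a number.
#'
#' @param predicted predicted labels (`NA` = uncertain).
#' @param truth true labels (`NA` = unknown, excluded).
#' @param exclude_uncertain drop uncertain predictions from the
#'   denominator instead of counting them as errors.
#' @return list of class `accuracy_report`: `accuracy`, `n_evaluated`,
#'   `n_correct`, `n_uncertain`, `n_missing_truth`, `confusion` (table
#'   over evaluated cases).
#' @examples
#' accuracy_report(c("a", "b", NA), c("a", "b", "b"), exclude_uncertain = TRUE)
#' @export
accuracy_report <- function(predicted, truth, exclude_uncertain = FALSE) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must have equal length")
  }
  known <- !is.na(truth)
  n_missing <- sum(!known)
  predicted <- predicted[known]
  truth <- truth[known]
  uncertain <- is.na(predicted)
  n_uncertain <- sum(uncertain)
  if (exclude_uncertain) {
    predicted <- predicted[!uncertain]
    truth <- truth[!uncertain]
  }
  n_eval <- length(truth)
  n_correct <- sum(!is.na(predicted) & predicted == truth)
  acc <- if (n_eval == 0L) NA_real_ else n_correct / n_eval
  conf <- table(truth = truth,
                predicted = ifelse(is.na(predicted), "<uncertain>", predicted))
  structure(list(accuracy = acc, n_evaluated = n_eval, n_correct = n_correct,
                 n_uncertain = n_uncertain, n_missing_truth = n_missing,
                 confusion = conf),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> accuracy:",
      if (is.na(x$accuracy)) "undefined (no evaluated cases)"
      else format(x$accuracy, digits = 4),
      "\n  evaluated:", x$n_evaluated, " correct:", x$n_correct,
      " uncertain:", x$n_uncertain, " missing truth:", x$n_missing_truth, "\n")
  invisible(x)
}

#' Bootstrap comparison of plain, reasonable and plausible Bayes
#'
#' Repeats the full pipeline on `B` bootstrap resamples (with
#' replacement, size `n`) of a labeled data set: refit the class model
#' on the resample, derive the evidence threshold from the resample's
#' empirical evidences, classify with all three rules, and score each
#' against the resample's truth labels. Replicates that lose an entire
#' class are redrawn (bounded retries). Besides the overall accuracies,
#' the same scores are computed on the replicate's low-evidence subset:
#' cases whose evidence lies below the replicate's 10th percentile
#' (type-7 quantile), where implausible Bayes assignments concentrate.
#' Aggregates are the replicate mean, SD and nonparametric 95% CI
#' (2.5th/97.5th percentile, type-7).
#'
#' @param x case table (`n x d`).
#' @param truth class label per case (`NA` allowed; such cases are
#'   resampled but never scored).
#' @param refit how to obtain the model on each replicate:
#'   `"labeled"` refits per-class Gaussians from the resample's labels
#'   (two-group scenarios); `"em"` refits a Gaussian mixture by EM and
#'   aligns fitted components to truth classes by the mean-distance
#'   minimizing permutation; `"none"` reuses `model` unchanged.
#' @param model a [bayes_model()]; required for `refit = "none"`,
#'   ignored otherwise.
#' @param B number of bootstrap replicates.
#' @param seed integer seed governing all resampling and refitting.
#' @param prior_mode prior mode for `refit = "labeled"`.
#' @param n_components mixture size for `refit = "em"`; default: number
#'   of truth classes.
#' @param n_restarts EM restarts per replicate (default 2; bootstrap
#'   refits start fresh on every replicate, so a small number keeps the
#'   experiment affordable).
#' @param epsilon_method,fraction threshold rule, see [compute_epsilon()].
#' @param low_evidence_quantile within-replicate evidence quantile
#'   defining the low-evidence subset (default 0.1).
#' @param max_redraws retries allowed when a resample loses a class.
#' @return list of class `bootstrap_report`: data frames `overall` and
#'   `low_evidence` (per method: mean, sd, ci_lower, ci_upper), the raw
#'   `replicates` accuracy matrices, `B`, `seed`, `n_redraws`, and
#'   `mean_epsilon` / `mean_flagged` summaries.
#' @export
bootstrap_experiment <- function(x, truth,
                                 refit = c("labeled", "em", "none"),
                                 model = NULL, B = 100, seed = NULL,
                                 prior_mode = "equal", n_components = NULL,
                                 n_restarts = 2,
                                 epsilon_method = c("abc", "fraction"),
                                 fraction = 0.01,
                                 low_evidence_quantile = 0.1,
                                 max_redraws = 100) {
  refit <- match.arg(refit)
  epsilon_method <- match.arg(epsilon_method)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  truth <- as.character(truth)
  if (length(truth) != nrow(x)) stop("'truth' must have one entry per case")
  if (all(is.na(truth))) stop("bootstrap evaluation needs labeled cases")
  if (B < 1L) stop("'B' must be >= 1")
  if (refit == "none" && is.null(model)) stop("refit = 'none' requires 'model'")
  classes <- sort(unique(stats::na.omit(truth)))
  if (is.null(n_components)) n_components <- length(classes)
  n <- nrow(x)
  methods <- c("bayes", "reasonable", "plausible")
  run_seeded(seed, {
    acc <- matrix(NA_real_, B, 3L, dimnames = list(NULL, methods))
    acc_low <- matrix(NA_real_, B, 3L, dimnames = list(NULL, methods))
    eps_used <- numeric(B)
    flagged <- numeric(B)
    n_redraws <- 0L
    for (b in seq_len(B)) {
      for (try in seq_len(max_redraws + 1L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (setequal(stats::na.omit(truth[idx]), classes)) break
        n_redraws <- n_redraws + 1L
        if (try > max_redraws) stop("could not draw a resample containing every class")
      }
      Xb <- x[idx, , drop = FALSE]
      tb <- truth[idx]
      mb <- switch(refit,
        labeled = {
          keep <- !is.na(tb)
          fit_from_labeled(Xb[keep, , drop = FALSE], tb[keep],
                           prior_mode = prior_mode)
        },
        em = {
          fit <- fit_gmm_em(Xb, n_components, n_restarts = n_restarts)
          match_components_to_truth(fit, Xb, tb)
        },
        none = model)
      res <- reasonable_bayes(mb, Xb, epsilon_method = epsilon_method,
                              fraction = fraction)
      res <- plausible_bayes(res)
      eps_used[b] <- attr(res, "epsilon")
      flagged[b] <- mean(is.na(res$reasonable))
      acc[b, ] <- c(
        accuracy_report(res$bayes, tb)$accuracy,
        accuracy_report(res$reasonable, tb, exclude_uncertain = TRUE)$accuracy,
        accuracy_report(res$plausible, tb)$accuracy)
      low <- res$evidence < stats::quantile(res$evidence,
                                            low_evidence_quantile, type = 7)
      acc_low[b, ] <- c(
        accuracy_report(res$bayes[low], tb[low])$accuracy,
        accuracy_report(res$reasonable[low], tb[low],
                        exclude_uncertain = TRUE)$accuracy,
        accuracy_report(res$plausible[low], tb[low])$accuracy)
    }
    if (n_redraws > 0L) {
      message(n_redraws, " resample(s) redrawn because a class was lost")
    }
    structure(
      list(overall = summarize_replicates(acc),
           low_evidence = summarize_replicates(acc_low),
           replicates = list(overall = acc, low_evidence = acc_low),
           B = B, seed = seed, n_redraws = n_redraws,
           mean_epsilon = mean(eps_used), mean_flagged = mean(flagged),
           refit = refit, epsilon_method = epsilon_method),
      class = "bootstrap_report")
  })
}

summarize_replicates <- function(m) {
  data.frame(
    method = colnames(m),
    mean = colMeans(m, na.rm = TRUE),
    sd = apply(m, 2L, stats::sd, na.rm = TRUE),
    ci_lower = apply(m, 2L, stats::quantile, 0.025, na.rm = TRUE, type = 7),
    ci_upper = apply(m, 2L, stats::quantile, 0.975, na.rm = TRUE, type = 7),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Rename EM components to truth class labels via the permutation that
# minimizes the total squared distance between fitted component means
# and the truth-group means.
match_components_to_truth <- function(model, x, truth) {
  classes <- sort(unique(stats::na.omit(truth)))
  if (length(classes) != length(model$components)) {
    stop("component/class count mismatch: ", length(model$components),
         " components vs ", length(classes), " classes")
  }
  gm <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(x[which(truth == cl), , drop = FALSE])
  }))
  fm <- model_means(model)
  c <- length(classes)
  if (c > 7L) stop("component matching by enumeration supports at most 7 classes")
  perms <- permutations(c)
  cost <- apply(perms, 1L, function(p) sum((fm - gm[p, , drop = FALSE])^2))
  map <- perms[which.min(cost), ]         # component k represents class map[k]
  comps <- model$components
  for (k in seq_len(c)) comps[[k]]$label <- classes[map[k]]
  ord <- order(vapply(comps, function(k) k$label, character(1L)))
  bayes_model(comps[ord], normalize = TRUE)
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("<bootstrap_report> B =", x$B, " refit:", x$refit,
      " threshold:", x$epsilon_method,
      sprintf(" (mean epsilon %.3g, mean flagged %.1f%%)\n",
              x$mean_epsilon, 100 * x$mean_flagged))
  cat("overall accuracy:\n")
  print(x$overall, digits = 4, row.names = FALSE)
  cat("low-evidence subset:\n")
  print(x$low_evidence, digits = 4, row.names = FALSE)
  invisible(x)
}
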