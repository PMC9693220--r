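#' @name scenarios
#' @title Synthetic scenario generators
#'
#' @description Seeded generators reproducing the statistical structure
#' of three situations in which low-evidence Bayes assignments become
#' implausible: sex-specific body heights of 11-year-olds, a serum
#' lipid biomarker with unequal group variances, and a two-dimensional
#' flow-cytometry-style three-population mixture. Each returns a
#' `scenario_dataset`: list with `data` (case-by-feature data frame),
#' `truth` (class label per case, `NA` where no ground truth exists),
#' `model` (the generating [bayes_model()]), `seed`, `scenario`.
#' Regeneration with the same seed is bit-identical, and the caller's
#' RNG state is left untouched.
NULL

scenario_dataset <- function(data, truth, model, seed, scenario) {
  structure(list(data = data, truth = truth, model = model,
                 seed = seed, scenario = scenario),
            class = "scenario_dataset")
}

#' @export
print.scenario_dataset <- function(x, ...) {
  cat("<scenario_dataset>", x$scenario, ":", nrow(x$data), "case(s),",
      ncol(x$data), "feature(s),", sum(!is.na(x$truth)), "labeled\n")
  invisible(x)
}

#' @rdname scenarios
#'
#' @details `generate_heights()` draws `n_per_sex` heights from
#' `N(149.8081, 0.5843)` (girls) and `N(151.0295, 0.5108)` (boys) — the
#' published mean and SD of 11-year-old German children — and appends
#' the 16 arbitrary heights 140, 142, ..., 170 cm, which carry no truth
#' label. Default size 100 + 100 + 16 = 216 cases. The stored model
#' uses equal priors.
#'
#' @param seed integer seed (optional but recommended).
#' @param n_per_sex simulated heights per sex.
#' @export
generate_heights <- function(seed = NULL, n_per_sex = 100) {
  m <- bayes_model(list(
    gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
    gaussian_component("boys", 151.0295, sd = 0.5108, weight = 0.5)))
  run_seeded(seed, {
    girls <- stats::rnorm(n_per_sex, 149.8081, 0.5843)
    boys <- stats::rnorm(n_per_sex, 151.0295, 0.5108)
    grid <- seq(140, 170, by = 2)
    scenario_dataset(
      data = data.frame(height = c(girls, boys, grid)),
      truth = c(rep("girls", n_per_sex), rep("boys", n_per_sex),
                rep(NA_character_, length(grid))),
      model = m, seed = seed, scenario = "heights")
  })
}

#' @rdname scenarios
#'
#' @details `generate_biomarker()` draws serum concentrations of the
#' ceramide C18Cer from `N(74.3881, 36.2643)` ng/mL for patients with
#' multiple sclerosis (default n = 102) and `N(86.8806, 29.8202)` for
#' healthy controls (default n = 301) — the published group moments and
#' sizes. The patient group has the lower mean but the larger SD, the
#' configuration that makes plain Bayes label very high values as
#' diseased. Faithful to the Gaussian model, negative concentrations
#' are possible and not truncated. The stored model uses equal priors.
#'
#' @param n_patients,n_controls group sizes.
#' @export
generate_biomarker <- function(seed = NULL, n_patients = 102, n_controls = 301) {
  m <- bayes_model(list(
    gaussian_component("control", 86.8806, sd = 29.8202, weight = 0.5),
    gaussian_component("patient", 74.3881, sd = 36.2643, weight = 0.5)))
  run_seeded(seed, {
    patients <- stats::rnorm(n_patients, 74.3881, 36.2643)
    controls <- stats::rnorm(n_controls, 86.8806, 29.8202)
    scenario_dataset(
      data = data.frame(c18cer = c(patients, controls)),
      truth = c(rep("patient", n_patients), rep("control", n_controls)),
      model = m, seed = seed, scenario = "biomarker")
  })
}

# Fixed constants of the cytometry-style scenario. Chosen to mimic the
# geometry of a CD45/CD13 scatter: one broad double-negative population
# and two tight positive populations whose heavy-tailed spread reaches
# into regions where the broad component's likelihood dominates.
cytometry_params <- function(tail_frac = 0.12, tail_scale = 4) {
  eff <- 1 - tail_frac + tail_frac * tail_scale^2   # tail-inflated variance factor
  list(
    weights = c(0.4, 0.3, 0.3),
    means = rbind(`1` = c(0, 0), `2` = c(8, 8), `3` = c(8, 0)),
    core_sd = c(1.5, 0.6, 0.6),
    tail_frac = tail_frac, tail_scale = tail_scale,
    # effective per-class covariances (what group moments converge to)
    cov = list(diag(1.5^2, 2L),
               diag(0.6^2 * eff, 2L),
               diag(0.6^2 * eff, 2L)))
}

#' @rdname scenarios
#'
#' @details `generate_cytometry()` emulates a two-marker (CD45/CD13)
#' cytometry scatter with three populations: class 1 = double negative
#' (nonleukocyte-like) at (0, 0), broad (core SD 1.5 per axis); class
#' 2 = double positive (myeloid-like) at (8, 8) and class 3 =
#' CD45+/CD13- (lymphocyte-like) at (8, 0), both tight (core SD 0.6).
#' Mixing weights are 0.4/0.3/0.3. As in real cytometry populations,
#' the tight classes are heavy-tailed: a fixed 12% of their events are
#' drawn with the SD scaled by 4 around the same center. The stored
#' generating model carries the effective per-class covariances
#' (`diag(2.25)` vs `diag(1.008)`), so the broad class has a
#' generalized variance about 5 times that of the others. The
#' construction guarantees a nonempty set of class-2/3 events whose
#' weighted likelihood is highest under the broad class-1 component —
#' the misassignment mechanism that nearest-center relabeling corrects.
#' All constants are fixture constants of this package, not estimates
#' of any real data set.
#'
#' @param n number of events (>= 100).
#' @export
generate_cytometry <- function(seed = NULL, n = 20000) {
  if (n < 100) stop("'n' must be at least 100")
  p <- cytometry_params()
  m <- bayes_model(lapply(1:3, function(k) {
    gaussian_component(as.character(k), p$means[k, ], cov = p$cov[[k]],
                       weight = p$weights[k])
  }))
  run_seeded(seed, {
    k <- sample.int(3L, n, replace = TRUE, prob = p$weights)
    infl <- ifelse(k > 1L & stats::runif(n) < p$tail_frac, p$tail_scale, 1)
    X <- cbind(stats::rnorm(n), stats::rnorm(n)) * (p$core_sd[k] * infl) +
      p$means[k, , drop = FALSE]
    scenario_dataset(
      data = data.frame(cd45 = X[, 1L], cd13 = X[, 2L]),
      truth = as.character(k),
      model = m, seed = seed, scenario = "cytometry")
  })
}

#' Generate a named scenario
#'
#' Dispatch helper used by the pipeline and the command line.
#'
#' @param scenario `"heights"`, `"biomarker"` or `"cytometry"`.
#' @param seed integer seed.
#' @param ... passed to the generator.
#' @return a `scenario_dataset`.
#' @export
generate_scenario <- function(scenario = c("heights", "biomarker", "cytometry"),
                              seed = NULL, ...) {
  scenario <- match.arg(scenario)
  switch(scenario,
         heights = generate_heights(seed, ...),
         biomarker = generate_biomarker(seed, ...),
         cytometry = generate_cytometry(seed, ...))
}
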