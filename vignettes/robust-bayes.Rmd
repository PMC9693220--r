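---
title: "Robust Bayes classification: evidence thresholding and nearest-center relabeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Bayes classification: evidence thresholding and nearest-center relabeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plausibayes)
```

## The model

A closed-world Bayes classifier assumes the data arise from `c`
exhaustive classes, each generating observations from a Gaussian
likelihood `N(m_k, s_k)` (univariate) or `N(m_k, Sigma_k)`
(multivariate), with prior weights `p(k)` summing to one. For a case
`x`,

* the **evidence** is `f(x) = Σ_k p(k) · φ_k(x)`, the mixture density —
  the overall probability of observing `x` at all;
* the **posterior** is `p(k | x) = p(k) · φ_k(x) / f(x)`;
* plain Bayes assigns `argmax_k p(k | x)`.

All densities are computed in log space and the evidence with
log-sum-exp, so posteriors remain well-defined far into the tails; a
case is only flagged as numerically undefined when every class log
density is `-Inf`, which finite inputs essentially never produce.

The failure mode this package addresses is structural, not numerical.
Posteriors are a *ratio*: they stay confidently near 0 or 1 even where
the evidence in the denominator is vanishingly small. Whenever one
class pairs a lower mean with a higher variance, its density dominates
both far tails and plain Bayes makes implausible calls exactly where
the model knows least. With the height model of 11-year-olds
(`N(149.8081, 0.5843)` girls vs `N(151.0295, 0.5108)` boys, equal
priors) the weighted likelihoods cross at 150.43 and 159.55 cm, so
everyone above 159.55 cm is called a girl.

```{r boundaries}
heights <- bayes_model(list(
  gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
  gaussian_component("boys",  151.0295, sd = 0.5108, weight = 0.5)))
decision_boundaries_1d(heights, c(140, 170))
```

Boundaries are found by scanning the pairwise log-weighted-likelihood
differences on an equidistant grid (4000 points by default) and
refining every sign change with `uniroot` to ~1e-8 feature units;
boundaries closer than 1e-4 are merged. Root refinement rather than a
grid scan makes the reported values resolution-independent.

## The evidence threshold ε

The reject option needs a cutoff: how little evidence is too little?
Two estimators are provided by `compute_epsilon()`:

* **Computed ABC analysis** (default). The positive evidence values are
  sorted in decreasing order; after the `i` largest items the *effort*
  is `i/n` and the *yield* their cumulative share of the total. Set A
  holds the "important few", set C the "trivial many". The B|C limit is
  operationalized as the *break-even point*: the last item whose value
  is at least the mean of all values — equivalently, whose per-item
  slope of the piecewise-linear yield curve is ≥ 1, the point where the
  profit gain stops exceeding the effort. ε is the first value past
  break-even (the largest member of C), and the downstream comparison
  is strict (`evidence < ε`), so with all values equal C is empty and
  nothing is flagged. The A|B limit (curve point closest to the ideal
  (0, 1)) is computed and reported for completeness but unused. For
  weakly skewed data the closest-to-ideal point can fall past the
  break-even point; in that case the A|B index is clamped to the B|C
  index (`exchanged = TRUE`, with the unconstrained `pareto_index`
  kept), which preserves the ordered A, B, C partition without touching
  ε. Published constructions of ABC limits differ in detail
  (interpolation, smoothing); this package implements exactly the
  break-even reading above and does not substitute another rule.
* **Fraction rule**: ε = 1% (configurable) of the maximum evidence.

Calibration on a standard normal, evaluated at 1000 equidistant grid
points, connects the two rules to familiar coverage:

```{r calibration}
ev <- evidence_grid(bayes_model(list(gaussian_component("z", 0, sd = 1))),
                    c(-5, 5), 1000)$evidence
sqrt(-2 * log(compute_epsilon(ev, "abc") * sqrt(2 * pi)))       # ~2 SD
sqrt(-2 * log(compute_epsilon(ev, "fraction") * sqrt(2 * pi)))  # ~3 SD
```

The ABC threshold keeps roughly `m ± 2s` (the half-width stays in
[1.4, 2.4] for grid half-widths between 4 and 8 SD), the 1% rule
`m ± 3s` (`sqrt(2 ln 100) = 3.035`). By default ε is estimated from the
*empirical* evidences of the cases being classified — the quantity the
threshold is meant to police; the grid variant exists for calibration
and for thresholding a model independently of a sample.

## Reasonable and plausible Bayes

`reasonable_bayes()` keeps the Bayes label where `evidence ≥ ε` and
returns the uncertain sentinel `NA` below — mirroring SQL's NULL/IEEE
NaN semantics; the sentinel is never a valid class label and serializes
as `NA` in CSV output. `plausible_bayes()` then assigns every uncertain
case to the class with the nearest center, where the centers are the
component means (the expected values of the class likelihoods):
`class(x) = argmin_k d(x, m_k)`.

For point queries this argmin *is* membership in the Voronoi cell of
the winning center, for any dimension, so no tessellation is built —
this sidesteps the dimensional limits of convex-hull based Voronoi
codes while being mathematically identical. The metric is raw
Euclidean by default; a per-feature z-scaling option
(`class_centers(..., metric = "zscore")`) exists for features on
incommensurate scales. Distance ties and posterior ties both resolve to
the lowest component index, keeping results deterministic and
order-stable. Certain labels are never touched, so the operation is
idempotent, and uncertain sets grow monotonically with ε.

## Fitting

`fit_from_labeled()` uses per-class sample moments. Priors default to
*equal* rather than group frequencies: the printed decision boundaries
of both univariate examples (150.43/159.55 cm; the 159 ng/mL biomarker
cutoff with groups of 102 vs 301) are reproduced only under equal
priors, which is also the natural choice when group sizes reflect
recruitment rather than prevalence. Frequency priors remain available
(`prior_mode = "proportional"`).

`fit_gmm_em()` is a classical EM fitter: k-means++-style seeding, 5
restarts by default (best final log-likelihood wins), convergence at a
relative log-likelihood change of 1e-6, covariance ridge
`1e-6 · trace/d` on singularity. The per-iteration log-likelihood trace
is stored so monotonicity is testable. EM component labels are
arbitrary; when fits must be scored against truth classes the bootstrap
aligns components to classes by the permutation minimizing the total
squared distance between component means and truth-group means.

## The synthetic scenarios

Three seeded generators make every stage testable without downloads.

* **Heights**: 100 draws per sex from the published `N(m, s)` pairs
  plus the 16 fixed grid heights 140, 142, ..., 170 cm, which carry no
  truth label (216 cases; evaluation skips unlabeled cases).
* **Biomarker**: C18Cer-like serum concentrations,
  `N(74.3881, 36.2643)` ng/mL for 102 patients and
  `N(86.8806, 29.8202)` for 301 controls — the lower-mean/higher-SD
  configuration. Faithful to the Gaussian model, negative
  concentrations can occur and are not truncated.
* **Cytometry**: a 2-D three-population mixture mimicking a CD45/CD13
  scatter: a broad double-negative class at (0, 0) (core SD 1.5,
  weight 0.4) and two tight classes at (8, 8) and (8, 0) (core SD 0.6,
  weight 0.3 each). Real cytometry populations spread wider than a
  single Gaussian core, and that spread is what makes low-evidence
  misassignment common rather than astronomically rare; the generator
  therefore draws a fixed 12% of each tight class's events with the SD
  scaled by 4 around the same center. The stored generating model
  carries the resulting effective covariances (diag 2.25 vs diag
  1.008; generalized-variance ratio ≈ 5), so group moments converge to
  the stored parameters. All constants are fixture constants chosen to
  reproduce the qualitative geometry — one broad component whose
  likelihood overtakes the tight classes' tails — not estimates of any
  real data set.

Because the tight classes are heavier-tailed than any single Gaussian,
an EM-fitted three-component model misassigns a visible share of their
stray events to the broad class, and nearest-center relabeling recovers
them. This is the mechanism the generator is built to exhibit. Passing
these tests shows the pipeline corrects that mechanism; it does not
show how large the gain is on any particular real data set, where
population shapes, class balance and the evidence distribution differ.

## Bootstrap evaluation

`bootstrap_experiment()` draws `B` resamples with replacement (B = 100
by default), refits the model on each replicate (labeled-moment refit
for two-group scenarios, EM refit for mixtures — refitting is the
standard bootstrap reading; a fixed-model variant is available),
derives ε from the replicate's empirical evidences, classifies with all
three rules and scores them against the replicate's truth. Aggregates
are the replicate mean, SD and nonparametric 95% CI (2.5th/97.5th
percentiles, type-7 linear interpolation throughout). The low-evidence
subset is the replicate's cases below its own 10th evidence percentile —
a within-replicate quantile, since "low" is relative to the sample at
hand. Replicates that lose an entire class are redrawn (bounded,
logged). With two EM restarts per replicate, B = 100 on 2000 cytometry
events runs in well under a minute; that problem size is used in the
package's own end-to-end checks.

On the cytometry scenario this reproduces the expected contrast: on the
lowest-evidence decile plausible Bayes is several points more accurate
than plain Bayes, while reasonable Bayes declines to classify nearly
the whole decile and reports an explicitly undefined accuracy there
(an empty denominator is `NA`, never a number). No claim is made that
plausible Bayes beats reasonable Bayes on classified-only cases; the
two answer different questions.

## Numerical choices and degenerate inputs

* Densities in log space; evidence via log-sum-exp; "evidence = 0" only
  when all class log densities underflow to `-Inf`.
* Univariate components store the SD `s` (the `N(m, s)` convention),
  multivariate ones a full covariance checked by Cholesky at
  construction.
* Model weights must sum to 1 within 1e-9 (closed world); a
  `normalize` flag rescales when convenient.
* ABC analysis requires strictly positive values and `n ≥ 2`; all-equal
  input yields an empty C and flags nothing.
* Zero-variance classes, duplicate class centers, dimension mismatches
  and non-numeric cells in input files are hard errors naming the
  offending class, row or column.
* All seeded entry points isolate their RNG use (`withr::with_seed`),
  so generation and fitting are bit-reproducible without disturbing the
  caller's stream.

## Known limitations

* Likelihoods are Gaussian only; no mixture-of-t or skewed families,
  which would model heavy-tailed populations directly instead of
  rejecting their tails.
* ε is derived from the total evidence, not per class; a per-class
  threshold variant is conceivable but unimplemented.
* The decision-boundary routine is univariate; multivariate decision
  surfaces are exercised implicitly through classification.
* Component-to-class alignment in the bootstrap enumerates
  permutations and is limited to ≤ 7 classes.
* The cytometry generator emulates two markers and three populations
  with documented constants; it does not emulate full multi-marker
  panels, instrument artefacts, or expert gating.
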