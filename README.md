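# plausibayes

Robust Bayesian classification for biomedical data: Gaussian-model
posteriors with a data-derived reject option ("reasonable Bayes") and
nearest-class-center relabeling of rejected cases ("plausible Bayes").

## The problem

Bayesian classifiers assign a case `x` to the class with the largest
posterior probability

```
p(class | x) = p(class) · likelihood_class(x) / evidence(x),
evidence(x)  = Σ_k p(k) · likelihood_k(x),
```

with Gaussian class likelihoods `N(m, s)`. The rule is optimal where the
data live, but it is not robust where the *evidence* — the overall
probability of observing `x` at all — is close to zero. When one class
has a lower mean but a larger variance than another, its density
dominates far out in *both* tails, so extreme values are confidently
assigned to the "typically smaller" class: a height model of 11-year-old
children ends up classifying every very tall person as a girl, and a
serum biomarker model assigns conspicuously *normal* concentrations to
the disease group. Flow-cytometry mixtures show the same pathology: a
broad double-negative population swallows the stray tails of tight
CD45+/CD13± populations.

`plausibayes` implements a two-step correction on top of standard
Gaussian/GMM Bayes classification, for anyone who classifies with
mixture models (cytometry gating, biomarker cutoffs, omics labels):

1. **Reasonable Bayes.** A threshold ε on the evidence is derived from
   the data by *computed ABC analysis*, a Pareto-type partition of the
   evidence values into sets A ("important few"), B (break-even) and C
   ("trivial many"); ε is the value at the B|C limit (alternatively,
   ε = 1% of the maximum evidence). Cases with `evidence < ε` get the
   uncertain sentinel `NA` instead of a forced label. For a normal
   distribution the ABC threshold keeps roughly `m ± 2s`, the 1% rule
   roughly `m ± 3s`.
2. **Plausible Bayes.** Cases left uncertain are reassigned to the class
   whose center (the component mean, the Voronoi cell generator) is
   nearest: `class(x) = argmin_k d(x, m_k)`. Tall people become boys
   again, and stray CD45+ events return to their populations.

The package also provides univariate decision-boundary computation, a
from-scratch EM fitter for Gaussian mixtures, seeded generators for
three benchmark scenarios (heights, biomarker, cytometry-style 2-D
mixture), and a 100-fold bootstrap harness that compares plain,
reasonable and plausible Bayes — overall and on the lowest-evidence
decile, where the correction matters.

## Worked example

```r
library(plausibayes)

heights <- bayes_model(list(
  gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
  gaussian_component("boys",  151.0295, sd = 0.5108, weight = 0.5)))

decision_boundaries_1d(heights, c(140, 170))
#> <decision_boundaries> 2 boundary/ies
#>   boundary class_a class_b
#> 1 150.4271   girls    boys
#> 2 159.5505   girls    boys

bayes_classify(heights, c(148, 155, 165))
#> [1] "girls" "boys"  "girls"
```

Between the two boundaries the classifier behaves sensibly; beyond
159.55 cm it calls everyone a girl — the 165 cm case above. The robust
pipeline suspends and then repairs such calls:

```r
sc <- generate_heights(seed = 1)            # 100 + 100 draws + 16 grid values
res <- reasonable_bayes(sc$model, sc$data)  # ABC threshold from the data
res <- plausible_bayes(res)
attr(res, "epsilon")
#> [1] 0.3196475
tall <- which(is.na(res$reasonable) & attr(res, "cases")[, 1] > 160)
head(res[tall, c("evidence", "bayes", "reasonable", "plausible")], 2)
#>          evidence bayes reasonable plausible
#> 212  9.797777e-96 girls       <NA>      boys
#> 213 2.685145e-129 girls       <NA>      boys
```

Every suspended case sits in the far tails (evidence below ε); the
nearest-center step hands the tall ones to the boys. The bootstrap
harness quantifies the gain where evidence is lowest:

```r
cy <- generate_cytometry(seed = 2026, n = 2000)
bootstrap_experiment(cy$data, cy$truth, refit = "em", B = 100,
                     seed = 2026, n_components = 3)
#> low-evidence subset:
#>      method   mean      sd ci_lower ci_upper
#>       bayes 0.8998 0.02363   0.8546   0.9450
#>  reasonable    NaN      NA       NA       NA
#>   plausible 0.9514 0.01382   0.9274   0.9749
```

On the within-replicate lowest-evidence decile, plausible Bayes lifts
the accuracy by about five points over plain Bayes; reasonable Bayes
reports no number there because it declines to classify nearly the whole
decile (that is its job).

A thin command-line wrapper covering `simulate`, `fit`, `threshold`,
`boundaries`, `classify`, `evaluate` and `run` is installed at
`system.file("cli", "plausibayes", package = "plausibayes")`.

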