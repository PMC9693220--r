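# Shared fixtures: the two published univariate two-class models and a
# random-model generator for property-style tests.

height_model <- function() {
  bayes_model(list(
    gaussian_component("girls", 149.8081, sd = 0.5843, weight = 0.5),
    gaussian_component("boys", 151.0295, sd = 0.5108, weight = 0.5)))
}

c18cer_model <- function() {
  bayes_model(list(
    gaussian_component("control", 86.8806, sd = 29.8202, weight = 0.5),
    gaussian_component("patient", 74.3881, sd = 36.2643, weight = 0.5)))
}

std_normal_model <- function() {
  bayes_model(list(gaussian_component("z", 0, sd = 1)))
}

# A random valid model: c components in d dimensions, random weights.
random_model <- function(d = 1L, c = 2L) {
  w <- runif(c, 0.1, 1)
  w <- w / sum(w)
  comps <- lapply(seq_len(c), function(k) {
    mu <- rnorm(d, sd = 3)
    if (d == 1L) {
      gaussian_component(paste0("k", k), mu, sd = runif(1, 0.2, 2), weight = w[k])
    } else {
      A <- matrix(rnorm(d * d), d)
      gaussian_component(paste0("k", k), mu,
                         cov = crossprod(A) + diag(0.1, d), weight = w[k])
    }
  })
  bayes_model(comps)
}

# Independent oracle for the Voronoi assignment: per-point loop over
# centers with the base distance function.
nearest_center_scan <- function(X, centers, labels) {
  vapply(seq_len(nrow(X)), function(i) {
    d <- vapply(seq_len(nrow(centers)), function(k) {
      sqrt(sum((X[i, ] - centers[k, ])^2))
    }, numeric(1L))
    labels[which.min(d)]
  }, character(1L))
}
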