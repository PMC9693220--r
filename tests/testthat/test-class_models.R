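test_that("gaussian_pdf matches the closed-form normal density", {
  z <- gaussian_component("z", 0, sd = 1)
  expect_equal(gaussian_pdf(z, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)

  # symmetry about the mean
  g <- gaussian_component("g", 149.8081, sd = 0.5843)
  a <- c(0.1, 0.5, 1, 2.5)
  expect_equal(gaussian_pdf(g, 149.8081 + a), gaussian_pdf(g, 149.8081 - a))

  # independent dnorm oracle (implementation evaluates its own log form)
  expect_equal(gaussian_pdf(g, 151), dnorm(151, 149.8081, 0.5843),
               tolerance = 1e-14)

  # multivariate density against the explicit quadratic-form formula
  S <- matrix(c(2, 0.6, 0.6, 1), 2)
  mv <- gaussian_component("m", c(1, -1), cov = S)
  x <- c(0.3, 0.2)
  q <- t(x - c(1, -1)) %*% solve(S) %*% (x - c(1, -1))
  ref <- exp(-q / 2) / (2 * pi * sqrt(det(S)))
  expect_equal(gaussian_pdf(mv, matrix(x, 1)), as.numeric(ref), tolerance = 1e-12)
})

test_that("component and model validation reject degenerate inputs", {
  expect_error(gaussian_component("a", 0, sd = -1), "positive")
  expect_error(gaussian_component("a", c(0, 0), cov = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(gaussian_component("a", 0, sd = 1, weight = 0), "\\(0, 1\\]")
  expect_error(gaussian_pdf(gaussian_component("a", c(0, 0), cov = diag(2)),
                            c(1, 2, 3)), "feature column")
  expect_error(bayes_model(list(
    gaussian_component("a", 0, sd = 1, weight = 0.6),
    gaussian_component("b", 1, sd = 1, weight = 0.6))), "sum to 1")
  expect_error(bayes_model(list(
    gaussian_component("a", 0, sd = 1, weight = 0.5),
    gaussian_component("a", 1, sd = 1, weight = 0.5))), "unique")
})

test_that("evidence is the prior-weighted likelihood sum", {
  one <- bayes_model(list(gaussian_component("only", 2, sd = 1.5)))
  x <- c(-1, 0, 2, 5)
  expect_equal(evidence(one, x), gaussian_pdf(one$components[[1]], x))

  twin <- bayes_model(list(
    gaussian_component("a", 2, sd = 1.5, weight = 0.3),
    gaussian_component("b", 2, sd = 1.5, weight = 0.7)))
  expect_equal(evidence(twin, x), gaussian_pdf(twin$components[[1]], x))

  # hand-summed weighted densities for the height model at 155 cm
  hand <- 0.5 * dnorm(155, 149.8081, 0.5843) + 0.5 * dnorm(155, 151.0295, 0.5108)
  expect_equal(evidence(height_model(), 155), hand, tolerance = 1e-12)
})

test_that("evidence is linear in the components (exact identity)", {
  set.seed(11)
  for (i in 1:50) {
    d <- sample(1:3, 1)
    m <- random_model(d, c = sample(2:4, 1))
    x <- matrix(rnorm(5 * d, sd = 4), ncol = d)
    per_comp <- vapply(m$components, function(k) gaussian_pdf(k, x), numeric(5))
    w <- vapply(m$components, function(k) k$weight, numeric(1))
    expect_equal(evidence(m, x), as.numeric(per_comp %*% w), tolerance = 1e-12)
  }
})

test_that("posteriors are normalized and proportional to weighted likelihoods", {
  # identical components, equal priors: posterior 0.5 everywhere
  twin <- bayes_model(list(
    gaussian_component("a", 0, sd = 1, weight = 0.5),
    gaussian_component("b", 0, sd = 1, weight = 0.5)))
  pt <- posterior_table(twin, c(-10, 0, 10))
  expect_equal(unname(pt$posteriors), matrix(0.5, 3, 2))

  # the implausible tail assignment: tall cases get high girl posterior
  pt <- posterior_table(height_model(), 165)
  expect_gt(pt$posteriors[1, "girls"], 0.5)

  # direct Bayes formula at 151.5 cm
  lik <- c(dnorm(151.5, 149.8081, 0.5843), dnorm(151.5, 151.0295, 0.5108))
  expect_equal(unname(posterior_table(height_model(), 151.5)$posteriors[1, ]),
               0.5 * lik / sum(0.5 * lik), tolerance = 1e-12)

  # normalization over random models and points
  set.seed(21)
  for (i in 1:200) {
    d <- sample(1:3, 1)
    m <- random_model(d, c = sample(1:4, 1))
    x <- matrix(rnorm(50 * d, sd = 5), ncol = d)
    p <- posterior_table(m, x)$posteriors
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
    expect_true(all(p >= 0))
  }
})

test_that("log-space posteriors survive evidence underflow; true -Inf is flagged", {
  # the evidence representation underflows to 0 here, but the log
  # densities are finite, so the posterior is still well-defined
  m <- bayes_model(list(
    gaussian_component("a", 0, sd = 1e-3, weight = 0.5),
    gaussian_component("b", 1, sd = 1e-3, weight = 0.5)))
  pt <- posterior_table(m, 10)
  expect_identical(pt$evidence[1], 0)
  expect_false(pt$underflow[1])
  expect_equal(sum(pt$posteriors[1, ]), 1)

  # only when every log density is -Inf is the case undefined
  z <- bayes_model(list(gaussian_component("a", 0, sd = 1)))
  pt2 <- posterior_table(z, 1e300)
  expect_true(pt2$underflow[1])
  expect_true(is.na(pt2$posteriors[1, 1]))
})

test_that("fit_from_labeled reproduces group moments and prior modes", {
  set.seed(5)
  x <- c(rnorm(102, 10, 2), rnorm(301, 20, 3))
  lab <- c(rep("p", 102), rep("h", 301))
  fit <- fit_from_labeled(x, lab, prior_mode = "equal")
  gh <- fit$components[[which(fit$labels == "h")]]
  expect_equal(gh$mean, mean(x[lab == "h"]))
  expect_equal(gh$sd, sd(x[lab == "h"]))
  expect_equal(vapply(fit$components, function(k) k$weight, numeric(1)),
               c(0.5, 0.5))
  prop <- fit_from_labeled(x, lab, prior_mode = "proportional")
  wp <- vapply(prop$components, function(k) k$weight, numeric(1))
  expect_equal(wp[prop$labels == "p"], 102 / 403)

  expect_error(fit_from_labeled(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               "zero variance")
  expect_error(fit_from_labeled(x, c(lab[-1], NA)), "NA")
})

test_that("fit_from_labeled recovers generating parameters within 3 SE", {
  set.seed(99)
  n <- 5000
  x <- c(rnorm(n, 3, 1.2), rnorm(n, 8, 0.7))
  lab <- rep(c("a", "b"), each = n)
  fit <- fit_from_labeled(x, lab)
  a <- fit$components[[1]]
  expect_lt(abs(a$mean - 3), 3 * 1.2 / sqrt(n))
  expect_lt(abs(a$sd - 1.2), 3 * 1.2 / sqrt(2 * n))
  b <- fit$components[[2]]
  expect_lt(abs(b$mean - 8), 3 * 0.7 / sqrt(n))
})

test_that("refitting data simulated from a fitted model converges to it", {
  set.seed(14)
  x <- c(rnorm(400, 5, 1), rnorm(400, 12, 2))
  lab <- rep(c("a", "b"), each = 400)
  fit1 <- fit_from_labeled(x, lab)
  n <- 1e5
  sim <- c(rnorm(n, fit1$components[[1]]$mean, fit1$components[[1]]$sd),
           rnorm(n, fit1$components[[2]]$mean, fit1$components[[2]]$sd))
  fit2 <- fit_from_labeled(sim, rep(c("a", "b"), each = n))
  for (k in 1:2) {
    expect_equal(fit2$components[[k]]$mean, fit1$components[[k]]$mean,
                 tolerance = 0.02)
    expect_equal(fit2$components[[k]]$sd, fit1$components[[k]]$sd,
                 tolerance = 0.02)
  }
})
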