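test_that("epsilon = 0 leaves no case uncertain", {
  r <- reasonable_bayes(height_model(), seq(140, 170, 0.5), epsilon = 0)
  expect_false(anyNA(r$reasonable))
  expect_identical(r$reasonable, r$bayes)
})

test_that("the evidence comparison is strict: below flags, at-threshold does not", {
  m <- height_model()
  x <- 144
  ev <- evidence(m, x)
  at <- reasonable_bayes(m, x, epsilon = ev)
  expect_false(is.na(at$reasonable))          # evidence == epsilon: kept
  above <- reasonable_bayes(m, x, epsilon = ev * (1 + 1e-9))
  expect_true(is.na(above$reasonable))        # evidence just below epsilon
})

test_that("ABC threshold flags only marginal heights", {
  sc <- generate_heights(seed = 6)
  r <- reasonable_bayes(sc$model, sc$data)
  flagged <- is.na(r$reasonable)
  expect_gt(sum(flagged), 0)
  expect_lt(sum(flagged), nrow(sc$data))
  # flagged cases live in the marginal regions where the pooled density
  # is very low: every flagged height lies beyond the span of the kept
  # ones, and every flagged evidence is below every kept evidence
  x <- sc$data$height
  expect_true(all(x[flagged] < min(x[!flagged]) | x[flagged] > max(x[!flagged])))
  expect_lt(max(r$evidence[flagged]), min(r$evidence[!flagged]))
})

test_that("uncertain sets grow monotonically with epsilon", {
  sc <- generate_heights(seed = 16)
  ev <- evidence(sc$model, sc$data)
  eps <- sort(c(quantile(ev, c(0.1, 0.3, 0.6), type = 7)))
  sets <- lapply(eps, function(e) which(is.na(
    reasonable_bayes(sc$model, sc$data, epsilon = e)$reasonable)))
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("class centers are the component means with distinct positions", {
  cc <- class_centers(height_model())
  expect_equal(unname(cc$centers[, 1]), c(149.8081, 151.0295))
  expect_identical(rownames(cc$centers), c("girls", "boys"))

  m <- generate_cytometry(seed = 2, n = 500)$model
  cc2 <- class_centers(m)
  expect_equal(nrow(cc2$centers), 3)
  expect_equal(unname(cc2$centers), rbind(c(0, 0), c(8, 8), c(8, 0)))

  dup <- bayes_model(list(
    gaussian_component("a", 0, sd = 1, weight = 0.5),
    gaussian_component("b", 0, sd = 2, weight = 0.5)))
  expect_error(class_centers(dup), "ill-defined")
})

test_that("plausible Bayes relabels tall uncertain cases as boys", {
  m <- height_model()
  r <- reasonable_bayes(m, 170, epsilon = evidence(m, 170) * 2)
  expect_true(is.na(r$reasonable))
  p <- plausible_bayes(r)
  expect_identical(p$plausible, "boys")      # 170 is nearer 151.03 than 149.81

  # a case exactly at a class mean belongs to that class
  r2 <- reasonable_bayes(m, 149.8081, epsilon = Inf)
  expect_identical(plausible_bayes(r2)$plausible, "girls")
})

test_that("nearest-center assignment equals the exhaustive Voronoi scan", {
  set.seed(9)
  m <- generate_cytometry(seed = 9, n = 200)$model
  X <- cbind(runif(2000, -6, 14), runif(2000, -6, 14))
  r <- plausible_bayes(reasonable_bayes(m, X, epsilon = Inf))
  cc <- class_centers(m)
  expect_identical(r$plausible, nearest_center_scan(X, cc$centers, cc$labels))
})

test_that("plausible Bayes preserves certain labels and is idempotent", {
  sc <- generate_cytometry(seed = 23, n = 1000)
  r <- reasonable_bayes(sc$model, sc$data)
  p1 <- plausible_bayes(r)
  keep <- !is.na(r$reasonable)
  expect_identical(p1$plausible[keep], r$reasonable[keep])
  expect_false(anyNA(p1$plausible))
  p2 <- plausible_bayes(p1)
  expect_identical(p2$plausible, p1$plausible)
})

test_that("distance ties go to the lowest class index", {
  m <- bayes_model(list(
    gaussian_component("left", -1, sd = 1, weight = 0.5),
    gaussian_component("right", 1, sd = 1, weight = 0.5)))
  r <- reasonable_bayes(m, 0, epsilon = Inf)
  expect_identical(plausible_bayes(r)$plausible, "left")
})

test_that("z-score metric rescales features before measuring distance", {
  m <- bayes_model(list(
    gaussian_component("a", c(0, 0), cov = diag(2), weight = 0.5),
    gaussian_component("b", c(10, 1), cov = diag(2), weight = 0.5)))
  # feature 1 spreads ~100x wider than feature 2 in these cases, so raw
  # distance is decided by feature 1 while the scaled one flips to
  # feature 2 for the first case
  X <- rbind(c(4, 0.9), c(-4, 0.95), c(6, 0.85), c(-6, 1.0), c(2, 0.88))
  r <- reasonable_bayes(m, X, epsilon = Inf)
  raw <- plausible_bayes(r, class_centers(m, "euclidean"))
  expect_identical(raw$plausible[1], "a")
  z <- plausible_bayes(r, class_centers(m, "zscore"))
  expect_identical(z$plausible[1], "b")
})
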