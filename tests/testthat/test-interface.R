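test_that("a written scenario reads back with identical values", {
  sc <- generate_heights(seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sc, f)
  back <- read_dataset(f, label_column = "label")
  expect_equal(back$data$height, sc$data$height)
  expect_identical(back$labels, sc$truth)
})

test_that("CSV and TSV of the same data parse identically", {
  sc <- generate_biomarker(seed = 7, n_patients = 20, n_controls = 30)
  fc <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(sc, fc)
  write_dataset(sc, ft)
  a <- read_dataset(fc, "label")
  b <- read_dataset(ft, "label")
  expect_identical(a, b)
})

test_that("non-numeric cells are rejected with the row and column named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "3,oops", "5,6"), f)
  expect_error(read_dataset(f), "row 2.*column 'y'")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y", f2)
  expect_error(read_dataset(f2), "empty")
  expect_error(read_dataset(f, label_column = "nope"), "not found")
  expect_error(read_dataset(file.path(tempdir(), "absent.csv")), "not found")
})

test_that("model configurations round-trip through JSON and YAML", {
  m <- c18cer_model()
  fj <- withr::local_tempfile(fileext = ".json")
  write_model_config(m, fj)
  expect_identical(read_model_config(fj)$components, m$components)

  mv <- bayes_model(list(
    gaussian_component("a", c(0, 0), cov = matrix(c(2, .5, .5, 1), 2), weight = 0.4),
    gaussian_component("b", c(3, 1), cov = diag(2), weight = 0.6)))
  fj2 <- withr::local_tempfile(fileext = ".json")
  write_model_config(mv, fj2)
  expect_identical(read_model_config(fj2)$components, mv$components)

  fy <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, fy)
  back <- read_model_config(fy)
  expect_equal(back$components, m$components, tolerance = 1e-12)
})

test_that("the pipeline runs a scenario end to end with provenance", {
  out <- withr::local_tempfile(fileext = ".csv")
  prov <- withr::local_tempfile(fileext = ".json")
  res <- run_pipeline(list(
    scenario = "heights", seed = 3, mode = "plausible",
    model = list(source = "labeled"),
    output = list(results = out, provenance = prov)))
  expect_s3_class(res$result, "classification_result")
  expect_true(all(c("bayes", "reasonable", "plausible") %in% names(res$result)))
  p <- jsonlite::read_json(prov, simplifyVector = TRUE)
  expect_equal(p$epsilon, attr(res$result, "epsilon"))
  expect_equal(p$seed, 3)
  expect_match(p$package, "plausibayes")
  expect_true(!is.null(p$version))
  expect_true(file.exists(out))
})

test_that("bayes-only mode omits the robust label columns", {
  res <- run_pipeline(list(scenario = "heights", seed = 3, mode = "bayes",
                           model = list(source = "labeled")))
  expect_false("reasonable" %in% names(res$result))
  expect_false("plausible" %in% names(res$result))
  expect_true("bayes" %in% names(res$result))
})

test_that("rerunning the same config and seed is bit-identical on disk", {
  cfg <- list(scenario = "biomarker", seed = 8, mode = "plausible",
              model = list(source = "labeled"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  run_pipeline(c(cfg, list(output = list(results = f1))))
  run_pipeline(c(cfg, list(output = list(results = f2))))
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("unknown configuration keys are rejected", {
  expect_error(run_pipeline(list(scenario = "heights", bogus = 1)), "unknown config key")
  expect_error(run_pipeline(list(scenario = "heights",
                                 model = list(wrong = 2))), "unknown config key")
  expect_error(run_pipeline(list(mode = "plausible")), "either 'input'")
  expect_error(run_pipeline(list(scenario = "heights", mode = "nope")), "mode")
})

test_that("stage errors are reported with the stage name", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x", "1", "oops"), f)
  expect_error(run_pipeline(list(input = f)), "stage data")
})
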