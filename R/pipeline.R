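pipeline_config_keys <- list(
  top = c("input", "scenario", "scenario_args", "label_column", "model",
          "epsilon", "metric", "mode", "evaluate", "seed", "output", "verbose"),
  model = c("source", "path", "n_components", "prior_mode", "n_restarts"),
  epsilon = c("method", "fraction", "source", "grid_n"),
  evaluate = c("bootstrap", "refit", "low_evidence_quantile"),
  output = c("results", "provenance", "report"))

validate_config <- function(config) {
  check <- function(x, keys, where) {
    unknown <- setdiff(names(x), keys)
    if (length(unknown)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  check(config, pipeline_config_keys$top, "config")
  for (sec in c("model", "epsilon", "evaluate", "output")) {
    if (!is.null(config[[sec]])) {
      check(config[[sec]], pipeline_config_keys[[sec]], sec)
    }
  }
  if (is.null(config$input) && is.null(config$scenario)) {
    stop("config needs either 'input' (a data file) or 'scenario'")
  }
  mode <- config$mode %||% "plausible"
  if (!mode %in% c("bayes", "reasonable", "plausible")) {
    stop("'mode' must be bayes, reasonable or plausible")
  }
  config
}

#' Run the full robust classification pipeline
#'
#' Composes the stages end to end: acquire data (file or synthetic
#' scenario), acquire the class model (configuration file, labeled fit,
#' or EM), derive the evidence threshold, classify (plain, reasonable,
#' plausible per `mode`), and optionally run the bootstrap evaluation
#' when truth labels are present. Deterministic under `seed`; progress
#' is logged to stderr when `verbose`.
#'
#' @param config a named list (or path to a JSON/YAML file holding one)
#'   with keys: `input` (CSV/TSV path) or `scenario` (name, plus
#'   optional `scenario_args`); `label_column`; `model` (list: `source`
#'   = `"config"`/`"labeled"`/`"em"`, `path`, `n_components`,
#'   `prior_mode`, `n_restarts`); `epsilon` (list: `method`, `fraction`,
#'   `source` = `"data"`/`"grid"`, `grid_n`); `metric`; `mode`
#'   (`"bayes"`, `"reasonable"`, `"plausible"`); `evaluate` (list:
#'   `bootstrap` = B, `refit`, `low_evidence_quantile`); `seed`;
#'   `output` (list: `results`, `provenance`, `report` paths);
#'   `verbose`. Unknown keys are rejected.
#' @return list with `result` (a `classification_result`, or a plain
#'   data frame of Bayes labels when `mode = "bayes"`), `model`,
#'   `report` (a `bootstrap_report` or `NULL`) and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      read_yaml_strict(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  config <- validate_config(config)
  verbose <- isTRUE(config$verbose)
  say <- function(...) if (verbose) message("[plausibayes] ", ...)
  seed <- config$seed

  # --- data ------------------------------------------------------------
  if (!is.null(config$input)) {
    say("stage data: reading ", config$input)
    ds <- tryCatch(read_dataset(config$input, config$label_column),
                   error = function(e) stop("stage data: ", conditionMessage(e)))
    X <- as.matrix(ds$data)
    truth <- ds$labels
  } else {
    say("stage data: generating scenario '", config$scenario, "'")
    sc <- do.call(generate_scenario,
                  c(list(scenario = config$scenario, seed = seed),
                    config$scenario_args %||% list()))
    X <- as.matrix(sc$data)
    truth <- sc$truth
  }

  # --- model -----------------------------------------------------------
  mc <- config$model %||% list()
  source <- mc$source %||% (if (!is.null(mc$path)) "config"
                            else if (!is.null(truth)) "labeled" else "em")
  say("stage model: source = ", source)
  model <- tryCatch(switch(source,
    config = read_model_config(mc$path),
    labeled = {
      if (is.null(truth)) stop("labeled fit requires a label column")
      keep <- !is.na(truth)
      fit_from_labeled(X[keep, , drop = FALSE], truth[keep],
                       prior_mode = mc$prior_mode %||% "equal")
    },
    em = fit_gmm_em(X, mc$n_components %||% 2L, seed = seed,
                    n_restarts = mc$n_restarts %||% 5),
    stop("unknown model source '", source, "'")),
    error = function(e) stop("stage model: ", conditionMessage(e)))

  # --- threshold -------------------------------------------------------
  ec <- config$epsilon %||% list()
  eps_method <- ec$method %||% "abc"
  eps_source <- ec$source %||% "data"
  ev <- if (identical(eps_source, "grid")) {
    evidence_grid(model, n = ec$grid_n %||% 1000)$evidence
  } else {
    evidence(model, X)
  }
  epsilon <- tryCatch(
    compute_epsilon(ev, method = eps_method, fraction = ec$fraction %||% 0.01),
    error = function(e) stop("stage threshold: ", conditionMessage(e)))
  say(sprintf("stage threshold: epsilon = %.6g (%s, %s evidence)",
              epsilon, eps_method, eps_source))

  # --- classification --------------------------------------------------
  mode <- config$mode %||% "plausible"
  if (mode == "bayes") {
    labels <- bayes_classify(model, X)
    result <- data.frame(case = seq_len(nrow(X)),
                         evidence = evidence(model, X),
                         bayes = labels, stringsAsFactors = FALSE)
    n_uncertain <- 0L
  } else {
    result <- reasonable_bayes(model, X, epsilon = epsilon)
    n_uncertain <- sum(is.na(result$reasonable))
    if (mode == "plausible") {
      centers <- class_centers(model, metric = config$metric %||% "euclidean")
      result <- plausible_bayes(result, centers)
    }
  }
  say("stage classify: mode = ", mode, ", ", n_uncertain, " uncertain case(s)")

  # --- evaluation ------------------------------------------------------
  report <- NULL
  if (!is.null(config$evaluate)) {
    if (is.null(truth) || all(is.na(truth))) {
      stop("stage evaluate: bootstrap evaluation requires truth labels")
    }
    evc <- config$evaluate
    refit <- evc$refit %||% (if (source == "em") "em" else "labeled")
    say("stage evaluate: B = ", evc$bootstrap %||% 100, ", refit = ", refit)
    report <- bootstrap_experiment(
      X, truth, refit = refit, model = model,
      B = evc$bootstrap %||% 100, seed = seed,
      n_components = mc$n_components %||% length(unique(stats::na.omit(truth))),
      epsilon_method = if (eps_method %in% c("abc", "fraction")) eps_method else "abc",
      fraction = ec$fraction %||% 0.01,
      low_evidence_quantile = evc$low_evidence_quantile %||% 0.1)
  }

  provenance <- list(
    package = "plausibayes",
    version = as.character(utils::packageVersion("plausibayes")),
    config = config, seed = seed, epsilon = epsilon,
    epsilon_method = eps_method, mode = mode,
    n_cases = nrow(X), n_uncertain = n_uncertain,
    set_sizes = if (eps_method == "abc") {
      lim <- abc_limits(abc_curve(ev))
      list(A = length(lim$A), B = length(lim$B), C = length(lim$C))
    })

  # --- output ----------------------------------------------------------
  oc <- config$output %||% list()
  if (!is.null(oc$results)) {
    say("writing results to ", oc$results)
    if (inherits(result, "classification_result")) {
      write_dataset(result, oc$results)
    } else {
      utils::write.table(result, oc$results, sep = ",", row.names = FALSE)
    }
  }
  if (!is.null(oc$provenance)) {
    jsonlite::write_json(provenance, oc$provenance, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  if (!is.null(oc$report) && !is.null(report)) {
    jsonlite::write_json(
      list(overall = report$overall, low_evidence = report$low_evidence,
           B = report$B, seed = report$seed, provenance = provenance),
      oc$report, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  list(result = result, model = model, report = report, provenance = provenance)
}
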