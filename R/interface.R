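#' Read a case table from CSV or TSV
#'
#' One case per row, numeric feature columns, header mandatory; comma
#' separator and "." decimal for `.csv`, tab for `.tsv`/`.tab`. An
#' optional label column is split off; empty cells and "NA" in it are
#' missing labels. Non-numeric feature cells are rejected with the row
#' and column named.
#'
#' @param path file path.
#' @param label_column name of the label column, or `NULL` for none.
#' @return list with `data` (numeric data frame) and `labels`
#'   (character or `NULL`).
#' @export
read_dataset <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (!nrow(raw) || !ncol(raw)) stop("empty data file: ", path)
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(raw)) {
      stop("label column '", label_column, "' not found in ", path)
    }
    labels <- raw[[label_column]]
    labels[labels %in% c("", "NA")] <- NA_character_
    raw[[label_column]] <- NULL
    if (!ncol(raw)) stop("no feature columns left after removing the label column")
  }
  data <- raw
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !(raw[[j]] %in% c("", "NA")))
    if (length(bad)) {
      stop("non-numeric value '", raw[[j]][bad[1L]], "' in row ", bad[1L],
           ", column '", names(raw)[j], "' of ", path)
    }
    if (anyNA(v)) {
      stop("missing value in row ", which(is.na(v))[1L], ", column '",
           names(raw)[j], "' of ", path)
    }
    data[[j]] <- v
  }
  list(data = data, labels = labels)
}

#' Write a scenario or classification to CSV
#'
#' @param x a `scenario_dataset` or `classification_result`.
#' @param path output path (`.csv` or `.tsv`). The uncertain sentinel is
#'   written as `NA`.
#' @export
write_dataset <- function(x, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  if (inherits(x, "scenario_dataset")) {
    out <- cbind(x$data, label = x$truth)
  } else if (inherits(x, "classification_result")) {
    out <- cbind(case = x$case, as.data.frame(attr(x, "cases")),
                 as.data.frame(x)[-1L])
  } else {
    out <- as.data.frame(x)
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read and write Bayes model configurations
#'
#' A model configuration is a list of classes, each with `label`,
#' `mean`, `sd` (univariate) or `cov` (row-major nested list), and
#' `weight`. JSON (`.json`) round-trips at full double precision; YAML
#' (`.yml`/`.yaml`) is also supported.
#'
#' @param path configuration file path.
#' @return [read_model_config()]: a [bayes_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    read_yaml_strict(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  classes <- cfg$classes %||% cfg
  comps <- lapply(classes, function(cl) {
    if (is.null(cl$label) || is.null(cl$mean) || is.null(cl$weight)) {
      stop("model config class needs 'label', 'mean' and 'weight'")
    }
    if (!is.null(cl$sd)) {
      gaussian_component(cl$label, unlist(cl$mean), sd = cl$sd, weight = cl$weight)
    } else if (!is.null(cl$cov)) {
      cov <- do.call(rbind, lapply(cl$cov, unlist))
      gaussian_component(cl$label, unlist(cl$mean), cov = cov, weight = cl$weight)
    } else {
      stop("model config class '", cl$label, "' needs 'sd' or 'cov'")
    }
  })
  bayes_model(unname(comps))
}

#' @rdname read_model_config
#' @param model a [bayes_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "bayes_model"))
  classes <- lapply(model$components, function(k) {
    out <- list(label = k$label, mean = k$mean, weight = k$weight)
    if (!is.null(k$sd)) out$sd <- k$sd
    else out$cov <- apply(k$cov, 1L, as.list, simplify = FALSE)
    out
  })
  cfg <- list(classes = classes)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path, precision = 17L)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
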