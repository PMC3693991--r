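# CSV / JSON readers and writers.
#
# Model-table CSV dialect: columns `id, smiles (optional), fingerprint,
# activity, logp (optional), pred_<MODEL1>, pred_<MODEL2>, ...`.  Errors are
# never stored in files: they are recomputed from activity and predictions on
# load, so a tampered or stale error column can never leak in.

#' Read and write model tables as CSV
#'
#' @param path File path.
#' @return `read_model_table()` returns a validated [model_table()] (with the
#'   fingerprint width enforced across rows and all validation errors
#'   reported with row numbers); `write_model_table()` returns `path`
#'   invisibly.
#' @export
read_model_table <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  types <- readr::cols(.default = readr::col_double())
  for (col in intersect(c("id", "fingerprint", "smiles"), header)) {
    types$cols[[col]] <- readr::col_character()
  }
  df <- readr::read_csv(path, col_types = types)
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  validate_model_table(df)
}

#' @param tbl A [model_table()].
#' @rdname read_model_table
#' @export
write_model_table <- function(tbl, path) {
  readr::write_csv(as_tibble(tbl), path)
  invisible(path)
}

#' Read and write tagged 2D point sets as CSV
#'
#' The plain-text points format: columns `compound_id`, `model_id`, `d`, `e`.
#'
#' @param points Data frame of tagged points.
#' @param path File path.
#' @export
read_points <- function(path) {
  as_points(readr::read_csv(
    path,
    col_types = readr::cols(
      compound_id = readr::col_character(),
      model_id = readr::col_character(),
      .default = readr::col_double()
    )
  ))
}

#' @rdname read_points
#' @export
write_points <- function(points, path) {
  readr::write_csv(as_points(points), path)
  invisible(path)
}

report_payload <- function(x, seed = NULL) {
  base <- list(
    package = "paretoqsar",
    version = as.character(utils::packageVersion("paretoqsar")),
    seed = seed
  )
  if (inherits(x, "pareto_loo")) {
    c(base, list(
      kind = "loo_evaluation",
      method = x$method, n = x$n, tau = x$tau,
      classification = x$classification,
      regression = x$regression,
      results = x$results
    ))
  } else if (inherits(x, "model_identification")) {
    c(base, list(
      kind = "identification",
      method = x$method, n = x$n, tau = x$tau,
      query_id = x$query_id,
      selected_model = x$selected_model,
      fallback_used = x$fallback_used,
      prediction = x$prediction,
      neighbourhood = x$neighbourhood,
      centroid = x$centroid,
      scores = x$scores
    ))
  } else if (is.list(x)) {
    c(base, x)
  } else {
    abort("cannot serialise this object as a report")
  }
}

#' Write an evaluation or identification report as JSON
#'
#' Serialises a [loo_evaluate()] report or an [identify()] result (or any
#' named list) with full-precision numbers, plus the package version and the
#' seed in use, so a run can be audited from its artifact alone.
#'
#' @param x Report object.
#' @param path Output path.
#' @param seed Optional seed to echo into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, seed = NULL) {
  jsonlite::write_json(
    report_payload(x, seed), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows",
    null = "null"
  )
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
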