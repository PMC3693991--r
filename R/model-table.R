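# The model table: chemicals x (fingerprint, measured activity, per-model
# predictions).  Stored as a wide tibble with one `pred_<MODEL>` column per
# model; absolute errors are always derived from activity and predictions,
# never stored, so the error identity e[i, m] = |y_i - y'_m(x_i)| holds by
# construction and survives any mutation or file round trip.

#' Build a model table from chemicals and prediction providers
#'
#' A model table is the working array of the identification framework: one
#' row per chemical with its identifier, fingerprint, measured activity and
#' one prediction column per model in the collection.  Predictions can be
#' supplied as literal `pred_<MODEL>` columns (outputs of external software
#' are data here) and/or generated by `models`, a named list of prediction
#' providers: either [linear_qsar()] objects (which require a `logp` column)
#' or functions taking the chemicals tibble and returning a numeric vector.
#'
#' @param chemicals Data frame with columns `id` (unique identifiers),
#'   `fingerprint` (bitstrings of equal width), `activity` (finite measured
#'   endpoint values), optional `logp` and `smiles`, and optional
#'   `pred_<MODEL>` columns.
#' @param models Optional named list of prediction providers; names become
#'   model names.
#'
#' @return A tibble of class `"model_table"` with at least two prediction
#'   columns.  Missing predictions may be `NA`: those (chemical, model) pairs
#'   are skipped when Pareto vectors are built.
#' @examples
#' chems <- data.frame(
#'   id = c("a", "b", "c"),
#'   fingerprint = c("1100", "1010", "0110"),
#'   activity = c(0.2, 0.5, 1.0),
#'   logp = c(1.1, 2.0, 2.9)
#' )
#' model_table(chems, qsar_igc50_models())
#' @export
model_table <- function(chemicals, models = NULL) {
  if (!is.data.frame(chemicals) || nrow(chemicals) == 0) {
    abort("`chemicals` must be a data frame with at least one row")
  }
  tbl <- as_tibble(chemicals)
  for (nm in names(models)) {
    provider <- models[[nm]]
    pred <- if (inherits(provider, "linear_qsar")) {
      if (!"logp" %in% names(tbl)) {
        abort(sprintf("model '%s' needs a `logp` column in `chemicals`", nm))
      }
      predict(provider, tbl$logp)
    } else if (is.function(provider)) {
      provider(tbl)
    } else {
      abort(sprintf(
        "prediction provider '%s' must be a linear_qsar model or a function", nm
      ))
    }
    if (!is.numeric(pred) || length(pred) != nrow(tbl)) {
      abort(sprintf(
        "prediction provider '%s' must return one number per chemical", nm
      ))
    }
    tbl[[paste0("pred_", nm)]] <- as.numeric(pred)
  }
  validate_model_table(tbl)
}

validate_model_table <- function(tbl) {
  required <- c("id", "fingerprint", "activity")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0("model table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl$id <- as.character(tbl$id)
  dup <- which(duplicated(tbl$id))
  if (length(dup)) {
    abort(sprintf("duplicate chemical id '%s' at row %d", tbl$id[dup[1]], dup[1]))
  }
  if (!is.numeric(tbl$activity) || anyNA(tbl$activity) ||
      !all(is.finite(tbl$activity))) {
    bad <- which(!is.finite(tbl$activity))[1]
    abort(sprintf("non-finite activity at row %d", bad))
  }
  m <- fp_matrix(tbl$fingerprint)
  zero <- which(rowSums(m) == 0)
  if (length(zero)) {
    abort(sprintf(
      "all-zero fingerprint at row %d: similarity would be undefined", zero[1]
    ))
  }
  preds <- grep("^pred_", names(tbl), value = TRUE)
  if (length(preds) < 2) {
    abort("a model table needs at least two prediction columns (pred_<MODEL>)")
  }
  for (p in preds) {
    if (!is.numeric(tbl[[p]])) abort(sprintf("column %s is not numeric", p))
  }
  class(tbl) <- c("model_table", class(as_tibble(tbl)))
  tbl
}

#' Accessors for a model table
#'
#' `model_names()` lists the model collection (from the `pred_` columns, in
#' column order); `prediction_matrix()` and `error_matrix()` return the
#' chemicals-by-models matrices of predictions and absolute errors
#' `|activity - prediction|`; `model_errors()` returns the same information
#' as a long tibble.
#'
#' @param tbl A model table (or any data frame in the model-table layout).
#' @return See each description; matrices carry chemical ids as row names and
#'   model names as column names.
#' @export
model_names <- function(tbl) {
  sub("^pred_", "", grep("^pred_", names(tbl), value = TRUE))
}

#' @rdname model_names
#' @export
prediction_matrix <- function(tbl) {
  cols <- grep("^pred_", names(tbl), value = TRUE)
  p <- as.matrix(as_tibble(tbl)[cols])
  dimnames(p) <- list(tbl$id, sub("^pred_", "", cols))
  p
}

#' @rdname model_names
#' @export
error_matrix <- function(tbl) {
  abs(tbl$activity - prediction_matrix(tbl))
}

#' @rdname model_names
#' @export
model_errors <- function(tbl) {
  long <- tidyr::pivot_longer(
    as_tibble(tbl)[c("id", "activity", grep("^pred_", names(tbl), value = TRUE))],
    cols = tidyr::starts_with("pred_"),
    names_to = "model", names_prefix = "pred_", values_to = "prediction"
  )
  long %>%
    mutate(error = abs(.data$activity - .data$prediction)) %>%
    select("id", "model", "activity", "prediction", "error")
}

#' @export
print.model_table <- function(x, ...) {
  cat(sprintf(
    "# Model table: %d chemicals x %d models (%s); %d-bit fingerprints\n",
    nrow(x), length(model_names(x)), paste(model_names(x), collapse = ", "),
    nchar(x$fingerprint[1])
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
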