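# Evaluation: oracle labels, leave-one-out identification, classification
# and regression reports, and the pairwise similarity-versus-activity table.

#' Oracle labels: the a-priori best model per chemical
#'
#' The oracle selector knows, for every chemical, which model of the
#' collection has the smallest absolute error; it upper-bounds what any
#' identification method can achieve.  Ties go to the first model in column
#' order.
#'
#' @param tbl A [model_table()].
#' @return Tibble with columns `id`, `model`.
#' @export
oracle_labels <- function(tbl) {
  tbl <- validate_model_table(as_tibble(tbl))
  err <- error_matrix(tbl)
  err[is.na(err)] <- Inf
  tibble(id = tbl$id, model = model_names(tbl)[apply(err, 1, which.min)])
}

#' Classification report against oracle labels
#'
#' Counts agreement between predicted model labels and oracle labels.  For a
#' designated positive class, `false_positive` counts chemicals assigned to
#' the positive class against the oracle and `false_negative` the reverse.
#' With more than one candidate class and no `positive_class`, one
#' one-vs-rest row is emitted per class (overall `correct`/`accuracy` are the
#' same in every row).
#'
#' @param predicted,oracle Character vectors of model labels, aligned by
#'   chemical.
#' @param model_names Optional character vector of valid labels (also fixes
#'   the default positive class: the first entry).
#' @param positive_class Optional single class for a one-row report.
#' @return Tibble with columns `positive_class`, `n`, `correct`,
#'   `false_positive`, `false_negative`, `accuracy`.
#' @export
classification_metrics <- function(predicted, oracle, model_names = NULL,
                                   positive_class = NULL) {
  if (length(predicted) != length(oracle) || length(predicted) == 0) {
    abort("`predicted` and `oracle` must be non-empty and the same length")
  }
  if (!is.null(model_names)) {
    bad <- setdiff(unique(c(predicted, oracle)), model_names)
    if (length(bad)) {
      abort(sprintf("label '%s' is not among the model names", bad[1]))
    }
  }
  classes <- positive_class %||% model_names %||% sort(unique(c(predicted, oracle)))
  if (!is.null(positive_class) && length(positive_class) != 1) {
    abort("`positive_class` must be a single model name")
  }
  n <- length(predicted)
  correct <- sum(predicted == oracle)
  purrr::map_dfr(classes, function(cls) {
    tibble(
      positive_class = cls,
      n = n,
      correct = correct,
      false_positive = sum(predicted == cls & oracle != cls),
      false_negative = sum(predicted != cls & oracle == cls),
      accuracy = correct / n
    )
  })
}

#' Regression report for observed versus predicted activities
#'
#' Computes `r2` (squared Pearson correlation), `rse` (residual standard
#' error of the simple linear regression of observed on predicted -- an
#' affine-invariant fit measure, so two models that are affine transforms of
#' one another share both `r2` and `rse`), `q2` (predictive squared
#' correlation, `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` with the mean
#' taken over the evaluated set), `mae` and `rmse`.
#'
#' @param observed,predicted Equal-length numeric vectors; at least 3
#'   complete pairs and a non-constant `observed` are required.
#' @return One-row tibble with `n`, `r2`, `rse`, `q2`, `mae`, `rmse`.
#' @export
regression_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must be the same length")
  }
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]
  predicted <- predicted[ok]
  if (length(observed) < 3) {
    abort("regression statistics need at least 3 complete pairs")
  }
  if (max(observed) == min(observed)) {
    abort("`observed` is constant: correlation statistics are undefined")
  }
  resid <- observed - predicted
  q2 <- 1 - sum(resid^2) / sum((observed - mean(observed))^2)
  mae <- mean(abs(resid))
  rmse <- sqrt(mean(resid^2))
  if (max(predicted) == min(predicted)) {
    warn("`predicted` is constant: r2 and rse are undefined (NA)")
    r2 <- NA_real_
    rse <- NA_real_
  } else {
    r2 <- cor(observed, predicted)^2
    fit <- lm(observed ~ predicted)
    rse <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  }
  tibble(n = length(observed), r2 = r2, rse = rse, q2 = q2,
         mae = mae, rmse = rmse)
}

#' Leave-one-out evaluation of an identification method
#'
#' Holds out each chemical in turn, identifies a model for it from the
#' remaining table, and scores the selections two ways: as a classification
#' against [oracle_labels()] of the full table, and as a regression of the
#' partitioning model's predictions (the selected model's stored prediction
#' for each held-out chemical) against the measured activities.
#'
#' @param tbl A [model_table()] with at least two chemicals.
#' @param method As in [identify()]; additionally `"oracle"` evaluates the
#'   oracle selector itself.
#' @param n,tau Neighbourhood parameters for bare methods.
#' @param positive_class Passed to [classification_metrics()]; defaults to
#'   the first model.
#' @param seed Optional seed for the randomized front search (results are
#'   seed-invariant).
#'
#' @return An object of class `"pareto_loo"`: a list with `results` (tibble:
#'   `id`, `activity`, `oracle`, `selected`, `correct`, `prediction`,
#'   `fallback`), `classification`, `regression` (NULL when fewer than 3
#'   predictions are available), `method`, `n`, `tau`.  [tidy()] returns the
#'   per-query rows, [glance()] the combined metrics.
#' @export
loo_evaluate <- function(tbl, method = "3-apmi", n = NULL, tau = NULL,
                         positive_class = NULL, seed = NULL) {
  spec <- resolve_method(method, n, tau)
  tbl <- validate_model_table(as_tibble(tbl))
  nc <- nrow(tbl)
  if (nc < 2) abort("leave-one-out needs at least two chemicals")
  if (!is.null(seed)) withr::local_seed(seed)

  mods <- model_names(tbl)
  err <- error_matrix(tbl)
  pred <- prediction_matrix(tbl)
  oracle <- oracle_labels(tbl)$model
  dist <- 1 - tanimoto_matrix(tbl$fingerprint)

  selected <- character(nc)
  fallback <- logical(nc)
  if (spec$base == "oracle") {
    selected <- oracle
  } else {
    for (i in seq_len(nc)) {
      rows <- seq_len(nc)[-i]
      res <- core_identify(
        dist[i, rows], err[rows, , drop = FALSE], tbl$id[rows], mods,
        spec$base, spec$n, spec$tau
      )
      selected[i] <- res$selected
      fallback[i] <- res$fallback
    }
  }
  prediction <- pred[cbind(seq_len(nc), match(selected, mods))]

  results <- tibble(
    id = tbl$id,
    activity = tbl$activity,
    oracle = oracle,
    selected = selected,
    correct = selected == oracle,
    prediction = prediction,
    fallback = fallback
  )
  classification <- classification_metrics(
    selected, oracle, mods, positive_class %||% mods[1]
  )
  regression <- if (sum(is.finite(prediction)) >= 3) {
    regression_metrics(tbl$activity, prediction)
  } else {
    warn("fewer than 3 predictions available: regression report omitted")
    NULL
  }
  structure(
    list(
      results = results,
      classification = classification,
      regression = regression,
      method = spec$label,
      n = spec$n,
      tau = spec$tau
    ),
    class = "pareto_loo"
  )
}

#' Whole-table regression statistics for each fixed model
#'
#' Scores every model of the collection on all chemicals at once (no
#' identification step) -- the baseline rows of a method-comparison table.
#'
#' @param tbl A [model_table()].
#' @return Tibble with one row per model: `model` plus the
#'   [regression_metrics()] columns.
#' @export
single_model_metrics <- function(tbl) {
  tbl <- validate_model_table(as_tibble(tbl))
  p <- prediction_matrix(tbl)
  purrr::map_dfr(model_names(tbl), function(m) {
    bind_cols(tibble(model = m), regression_metrics(tbl$activity, p[, m]))
  })
}

#' @export
print.pareto_loo <- function(x, ...) {
  cat(sprintf("<pareto_loo> method %s over %d chemicals\n",
              x$method, nrow(x$results)))
  cat("Classification vs oracle:\n")
  print(x$classification, ...)
  if (!is.null(x$regression)) {
    cat("Regression (partitioning-model predictions):\n")
    print(x$regression, ...)
  }
  invisible(x)
}

#' Pairwise similarity-versus-activity count table
#'
#' Compares all unordered pairs of chemicals: for each pair the Tanimoto
#' distance `d = 1 - S_T` and the absolute activity difference are computed,
#' and cell (r, c) counts the pairs with `d <= sim_thresholds[r]` and
#' difference `<= act_thresholds[c]`.  Counts are cumulative and thresholds
#' inclusive, so cells are monotone along rows and columns; the table
#' summarises how far the "similar structure, similar activity" hypothesis
#' holds in a dataset.
#'
#' @param tbl A [model_table()] or data frame with `fingerprint`, `activity`.
#' @param sim_thresholds,act_thresholds Increasing numeric thresholds for the
#'   Tanimoto distance (rows) and activity difference (columns).
#' @return Tibble: first column `f_sim`, one column per activity threshold.
#' @export
similarity_activity_table <- function(tbl,
                                      sim_thresholds = seq(0, 0.5, by = 0.1),
                                      act_thresholds = seq(0, 1.5, by = 0.1)) {
  if (!is.data.frame(tbl) || nrow(tbl) < 2) {
    abort("need at least two chemicals to form pairs")
  }
  sim <- tanimoto_matrix(tbl$fingerprint)
  up <- upper.tri(sim)
  dvec <- (1 - sim)[up]
  avec <- abs(outer(tbl$activity, tbl$activity, "-"))[up]
  counts <- vapply(
    act_thresholds,
    function(a) vapply(
      sim_thresholds,
      function(s) sum(dvec <= s & avec <= a),
      integer(1)
    ),
    integer(length(sim_thresholds))
  )
  counts <- matrix(counts, nrow = length(sim_thresholds))
  out <- as_tibble(counts, .name_repair = ~ as.character(act_thresholds))
  bind_cols(tibble(f_sim = sim_thresholds), out)
}
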