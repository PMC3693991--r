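# broom-style tidiers for the package's result objects.

#' Tidy and glance methods
#'
#' `tidy()` returns the per-element table of a result (front points, model
#' scores, per-query rows); `glance()` a one-row summary.
#'
#' @param x A `pareto_front`, `model_identification` or `pareto_loo` object.
#' @param ... Unused.
#' @return A tibble.
#' @name paretoqsar-tidiers
NULL

#' @rdname paretoqsar-tidiers
#' @export
tidy.pareto_front <- function(x, ...) as_tibble(x)

#' @rdname paretoqsar-tidiers
#' @export
glance.pareto_front <- function(x, ...) {
  b <- attr(x, "bounds")
  tibble(
    n_points = nrow(attr(x, "input")),
    n_front = nrow(x),
    n_initial = nrow(attr(x, "initial")),
    f1_min = unname(b["f1_min"]), f1_max = unname(b["f1_max"]),
    f2_min = unname(b["f2_min"]), f2_max = unname(b["f2_max"])
  )
}

#' @rdname paretoqsar-tidiers
#' @export
tidy.model_identification <- function(x, ...) {
  mutate(x$scores, selected = .data$model == x$selected_model)
}

#' @rdname paretoqsar-tidiers
#' @export
glance.model_identification <- function(x, ...) {
  tibble(
    query_id = x$query_id,
    method = x$method,
    selected_model = x$selected_model,
    n_neighbours = nrow(x$neighbourhood),
    fallback_used = x$fallback_used,
    prediction = x$prediction
  )
}

#' @rdname paretoqsar-tidiers
#' @export
tidy.pareto_loo <- function(x, ...) x$results

#' @rdname paretoqsar-tidiers
#' @export
glance.pareto_loo <- function(x, ...) {
  cls <- x$classification[1, ]
  out <- tibble(
    method = x$method,
    n = cls$n,
    correct = cls$correct,
    accuracy = cls$accuracy
  )
  if (!is.null(x$regression)) out <- bind_cols(out, x$regression[-1])
  out
}
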