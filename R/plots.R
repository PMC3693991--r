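# ggplot2 visualisations of fronts, identifications and LOO reports.

#' Plot a Pareto front over its point cloud
#'
#' Dominated points in grey, front points connected by a staircase in the
#' order of increasing distance, initial-set members highlighted.
#'
#' @param object A [pareto_front()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_front <- function(object, ...) {
  all_pts <- attr(object, "input")
  front <- arrange(as_tibble(object), .data$d, .data$e)
  init <- attr(object, "initial")
  ggplot2::ggplot(all_pts, ggplot2::aes(x = .data$d, y = .data$e)) +
    ggplot2::geom_point(colour = "grey60", size = 1.5) +
    ggplot2::geom_step(data = front, direction = "vh", colour = "#2166ac") +
    ggplot2::geom_point(data = front, colour = "#2166ac", size = 2) +
    ggplot2::geom_point(data = init, shape = 21, size = 3.5,
                        colour = "#b2182b", fill = NA, stroke = 1) +
    ggplot2::labs(
      x = "Tanimoto distance to query (d)",
      y = "model error (e)",
      title = sprintf("Pareto front: %d of %d points", nrow(front), nrow(all_pts))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an identification result
#'
#' The neighbourhood points labelled by model, with the centroid marked for
#' CPMI selections.
#'
#' @param object A [identify()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_identification <- function(object, ...) {
  nb <- object$neighbourhood
  p <- ggplot2::ggplot(
    nb, ggplot2::aes(x = .data$d, y = .data$e, colour = .data$model_id)
  ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "Tanimoto distance to query (d)", y = "model error (e)",
      colour = "model",
      title = sprintf("%s: query %s -> %s",
                      object$method, object$query_id, object$selected_model)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$centroid)) {
    p <- p + ggplot2::geom_point(
      data = object$centroid,
      ggplot2::aes(x = .data$d_c, y = .data$e_c),
      inherit.aes = FALSE, shape = 4, size = 4, stroke = 1.2
    )
  }
  p
}

#' Plot a leave-one-out evaluation
#'
#' Observed versus partitioning-model predicted activity, coloured by
#' whether the selected model agreed with the oracle.
#'
#' @param object A [loo_evaluate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_loo <- function(object, ...) {
  res <- filter(object$results, is.finite(.data$prediction))
  ggplot2::ggplot(
    res,
    ggplot2::aes(x = .data$activity, y = .data$prediction,
                 colour = .data$correct)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "measured activity", y = "identified-model prediction",
      colour = "oracle agreement",
      title = sprintf("Leave-one-out, method %s", object$method)
    ) +
    ggplot2::theme_minimal()
}
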