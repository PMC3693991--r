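# Single-descriptor linear QSAR models.
#
# The two bundled narcosis models predict Tetrahymena pyriformis toxicity,
# log(1/IGC50), as an affine function of logP (octanol-water partition
# coefficient): non-polar narcosis (NPN) 0.83*logP - 2.07 and polar narcosis
# (PN) 0.62*logP - 1.00.  Because both are affine in the same descriptor,
# correlation-based statistics (R2, RSE) of the two coincide on any chemical
# set -- a fact the evaluation module exploits as a consistency check.

#' Construct a linear (affine) single-descriptor QSAR model
#'
#' @param name Model identifier.
#' @param slope,intercept Coefficients of `slope * logP + intercept`.
#' @return An object of class `"linear_qsar"`.
#' @examples
#' npn <- linear_qsar("NPN", 0.83, -2.07)
#' predict(npn, logp = 1.5)
#' @export
linear_qsar <- function(name, slope, intercept) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("`name` must be a non-empty string")
  }
  if (!is.finite(slope) || !is.finite(intercept)) {
    abort("`slope` and `intercept` must be finite")
  }
  structure(
    list(name = name, slope = slope, intercept = intercept),
    class = "linear_qsar"
  )
}

#' @param object A `"linear_qsar"` model.
#' @param logp Numeric vector of logP values; must be finite (a chemical with
#'   no logP cannot be scored by these models).
#' @param ... Unused.
#' @rdname linear_qsar
#' @export
predict.linear_qsar <- function(object, logp, ...) {
  if (!is.numeric(logp) || anyNA(logp) || !all(is.finite(logp))) {
    abort(sprintf(
      "model '%s' needs a finite logP value for every chemical", object$name
    ))
  }
  object$slope * logp + object$intercept
}

#' @export
print.linear_qsar <- function(x, ...) {
  cat(sprintf(
    "<linear_qsar> %s: prediction = %g * logP + %g\n",
    x$name, x$slope, x$intercept
  ))
  invisible(x)
}

#' The bundled polar / non-polar narcosis IGC50 models
#'
#' @return Named list with the `PN` (0.62 * logP - 1.00) and `NPN`
#'   (0.83 * logP - 2.07) models for log(1/IGC50).
#' @export
qsar_igc50_models <- function() {
  list(
    PN = linear_qsar("PN", 0.62, -1.00),
    NPN = linear_qsar("NPN", 0.83, -2.07)
  )
}
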