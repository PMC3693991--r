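# Binary fingerprints and Tanimoto similarity.
#
# Fingerprints travel as '0'/'1' bitstrings (CSV-friendly) and are expanded to
# 0/1 integer matrices for arithmetic.  All-zero fingerprints are rejected at
# validation time: a featureless molecule cannot take part in similarity
# search and would make the Tanimoto coefficient 0/0.

#' Expand bitstring fingerprints to a 0/1 matrix
#'
#' @param x Character vector of fingerprints (strings over `{0,1}`), or an
#'   already-expanded numeric/logical matrix, one row per chemical.
#' @param width Expected fingerprint width.  Defaults to the width of the
#'   first fingerprint; every row must match it.
#'
#' @return Integer matrix with one row per fingerprint and one column per bit.
#' @examples
#' fp_matrix(c("1100", "1010"))
#' @export
fp_matrix <- function(x, width = NULL) {
  if (is.matrix(x)) {
    if (!all(x %in% c(0, 1))) {
      abort("fingerprint matrix must contain only 0/1 values")
    }
    return(matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x)))
  }
  if (!is.character(x) || length(x) == 0) {
    abort("fingerprints must be a non-empty character vector of bitstrings")
  }
  bad <- which(!grepl("^[01]+$", x))
  if (length(bad)) {
    abort(sprintf("fingerprint at row %d contains non-binary characters", bad[1]))
  }
  w <- nchar(x)
  width <- width %||% w[1]
  off <- which(w != width)
  if (length(off)) {
    abort(sprintf(
      "fingerprint width mismatch at row %d: expected %d bits, found %d",
      off[1], width, w[off[1]]
    ))
  }
  out <- t(vapply(x, function(s) utf8ToInt(s) - 48L, integer(width), USE.NAMES = FALSE))
  out
}

as_bits <- function(f) {
  if (is.character(f)) {
    if (length(f) != 1) abort("a single fingerprint must be one bitstring")
    return(drop(fp_matrix(f)))
  }
  if (is.logical(f)) f <- as.integer(f)
  if (!is.numeric(f) || !all(f %in% c(0L, 1L))) {
    abort("a fingerprint must be a bitstring or a 0/1 vector")
  }
  as.integer(f)
}

#' Tanimoto similarity and distance between two fingerprints
#'
#' The Tanimoto (Jaccard) coefficient for binary fingerprints is
#' \eqn{S_T(a, b) = |a \wedge b| / |a \vee b|}: the number of bits set in both
#' fingerprints over the number of bits set in either.  The associated
#' distance is \eqn{d = 1 - S_T}, the first coordinate of the model
#' identification space.
#'
#' @param a,b Fingerprints: bitstrings or 0/1 vectors of equal length.
#'
#' @return A number in `[0, 1]`.  Undefined (an error) when both fingerprints
#'   have no set bits.
#' @examples
#' tanimoto("1100", "1010") # 1/3
#' tanimoto_distance("1100", "1010") # 2/3
#' @export
tanimoto <- function(a, b) {
  a <- as_bits(a)
  b <- as_bits(b)
  if (length(a) != length(b)) {
    abort(sprintf(
      "fingerprint length mismatch: %d vs %d bits", length(a), length(b)
    ))
  }
  union <- sum(a | b)
  if (union == 0) {
    abort("Tanimoto similarity is undefined for two all-zero fingerprints")
  }
  sum(a & b) / union
}

#' @rdname tanimoto
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto(a, b)

#' Pairwise Tanimoto similarity matrix
#'
#' @inheritParams fp_matrix
#' @return Symmetric numeric matrix of similarities with unit diagonal.
#' @export
tanimoto_matrix <- function(x, width = NULL) {
  m <- fp_matrix(x, width)
  ones <- rowSums(m)
  if (any(ones == 0)) {
    abort(sprintf("all-zero fingerprint at row %d", which(ones == 0)[1]))
  }
  common <- tcrossprod(m)
  union <- outer(ones, ones, "+") - common
  common / union
}

# Distances from one query fingerprint (0/1 vector) to the rows of a 0/1
# matrix; vectorized hot path shared by identify() and loo_evaluate().
query_tanimoto_distance <- function(qbits, m) {
  ones <- rowSums(m)
  nq <- sum(qbits)
  if (nq == 0) abort("query fingerprint has no set bits")
  if (any(ones == 0)) abort("all-zero fingerprint in the model table")
  common <- as.vector(m %*% qbits)
  1 - common / (ones + nq - common)
}
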