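# Two-dimensional Pareto order and front computation.
#
# A point set lives in a tibble with columns `d` and `e` (distance, error)
# plus optional `compound_id` / `model_id` tags.  "Minimal" is taken downward:
# a point is on the front when no other point is coordinate-wise <= it with at
# least one strict inequality.  Comparisons are exact -- coordinates come from
# integer bit counts and short decimals, and a tolerance would silently merge
# distinct front points.

check_pair <- function(v, w) {
  if (length(v) != 2 || length(w) != 2 || !all(is.finite(c(v, w)))) {
    abort("vectors must be length-2 with finite coordinates")
  }
}

#' Coordinate-wise dominance predicates in two dimensions
#'
#' `dominated_by(v, w)` tests the coordinate-wise order `v` \eqn{\preceq} `w`
#' (every coordinate of `v` is no larger than the matching coordinate of
#' `w`).  `strictly_dominated_by()` additionally requires `v != w`, and
#' `incomparable()` holds when neither vector precedes the other --
#' equivalently, one coordinate is strictly smaller and the other strictly
#' larger.
#'
#' @param v,w Numeric vectors of length 2 with finite coordinates.
#' @return A single logical.
#' @examples
#' dominated_by(c(0, 0), c(1, 2))
#' incomparable(c(0, 2), c(1, 0))
#' @export
dominated_by <- function(v, w) {
  check_pair(v, w)
  v[1] <= w[1] && v[2] <= w[2]
}

#' @rdname dominated_by
#' @export
strictly_dominated_by <- function(v, w) {
  dominated_by(v, w) && (v[1] != w[1] || v[2] != w[2])
}

#' @rdname dominated_by
#' @export
incomparable <- function(v, w) {
  !dominated_by(v, w) && !dominated_by(w, v)
}

# Normalise any data frame carrying d/e (+ optional tags) into the canonical
# tagged-point tibble.
as_points <- function(points) {
  if (!is.data.frame(points)) {
    abort("`points` must be a data frame with columns `d` and `e`")
  }
  points <- as_tibble(points)
  if (!all(c("d", "e") %in% names(points))) {
    abort("`points` must have columns `d` and `e`")
  }
  if (nrow(points) > 0 && !all(is.finite(points$d), is.finite(points$e))) {
    abort("point coordinates must be finite")
  }
  if (!"compound_id" %in% names(points)) {
    points$compound_id <- as.character(seq_len(nrow(points)))
  }
  if (!"model_id" %in% names(points)) {
    points$model_id <- rep("", nrow(points))
  }
  select(points, "compound_id", "model_id", "d", "e")
}

# Indices of the minimal (non-strictly-dominated-downward) points; fully
# vectorized O(n^2) all-pairs scan, the reference oracle.
brute_idx <- function(d, e) {
  n <- length(d)
  if (n == 0) return(integer(0))
  led <- outer(d, d, "<=")
  lee <- outer(e, e, "<=")
  lt <- outer(d, d, "<") | outer(e, e, "<")
  dominated <- colSums(led & lee & lt) > 0
  which(!dominated)
}

# Random-descent search for one minimal point within the subset `idx`:
# start from a uniformly random candidate and repeatedly move to the first
# point (in scan order) strictly coordinate-wise below it.  Worst case O(n^2)
# on a chain; the result set of the front computation is seed-invariant.
descent_idx <- function(d, e, idx) {
  cur <- idx[sample.int(length(idx), 1L)]
  repeat {
    below <- idx[(d[idx] < d[cur] & e[idx] <= e[cur]) |
                   (d[idx] <= d[cur] & e[idx] < e[cur])]
    if (!length(below)) return(cur)
    cur <- below[1]
  }
}

# Divide-and-conquer front computation with an explicit work stack (the front
# can be as large as the input, so no recursion-depth failures).  Each step
# finds a minimal point g, emits g together with every point sharing its
# coordinates, drops the closed upper quadrant of g, and pushes the two open
# quadrants (d < g_d & e > g_e) and (d > g_d & e < g_e).
front_idx <- function(d, e) {
  n <- length(d)
  if (n == 0) return(integer(0))
  keep <- integer(0)
  stack <- list(seq_len(n))
  while (length(stack)) {
    idx <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    g <- descent_idx(d, e, idx)
    gd <- d[g]
    ge <- e[g]
    di <- d[idx]
    ei <- e[idx]
    keep <- c(keep, idx[di == gd & ei == ge])
    lower <- idx[di < gd & ei > ge]
    upper <- idx[di > gd & ei < ge]
    if (length(lower)) stack <- c(stack, list(lower))
    if (length(upper)) stack <- c(stack, list(upper))
  }
  sort(keep)
}

#' Initial Pareto set and search-rectangle bounds
#'
#' The initial Pareto set collects, for each coordinate, the points achieving
#' the per-coordinate minimum that are minimal on the other coordinate.  In
#' two dimensions it holds at most two distinct coordinate pairs, every
#' member belongs to the full Pareto front, and its coordinate extremes bound
#' the rectangle that can contain further front points.
#'
#' @param points Data frame with numeric columns `d`, `e` and optional
#'   `compound_id`, `model_id` tags.
#'
#' @return A list with `points` (tibble of initial-set members; points that
#'   share the minimal coordinates are all retained) and `bounds`, a named
#'   numeric vector `f1_min`, `f1_max`, `f2_min`, `f2_max` (minima over the
#'   input, maxima over the initial set).
#' @examples
#' initial_pareto_set(data.frame(d = c(1, 2, 4), e = c(5, 3, 1)))
#' @export
initial_pareto_set <- function(points) {
  pts <- as_points(points)
  if (nrow(pts) == 0) abort("`points` is empty")
  d <- pts$d
  e <- pts$e
  f1_min <- min(d)
  f2_min <- min(e)
  g1 <- which(d == f1_min & e == min(e[d == f1_min]))
  g2 <- which(e == f2_min & d == min(d[e == f2_min]))
  ig <- sort(unique(c(g1, g2)))
  list(
    points = pts[ig, ],
    bounds = c(
      f1_min = f1_min, f1_max = max(d[ig]),
      f2_min = f2_min, f2_max = max(e[ig])
    )
  )
}

#' Find one Pareto-minimal point by random descent
#'
#' Picks a uniformly random candidate and repeatedly replaces it with a point
#' strictly coordinate-wise smaller until none exists.  Any returned point is
#' minimal in `points`; which minimal point is returned depends on the seed.
#'
#' @inheritParams initial_pareto_set
#' @param seed Optional integer seed for the internal random choices.
#' @return One-row tibble, a member of the Pareto front of `points`.
#' @export
find_pareto_point <- function(points, seed = NULL) {
  pts <- as_points(points)
  if (nrow(pts) == 0) abort("`points` is empty")
  if (!is.null(seed)) withr::local_seed(seed)
  pts[descent_idx(pts$d, pts$e, seq_len(nrow(pts))), ]
}

#' Two-dimensional Pareto front of a tagged point set
#'
#' `pareto_front()` returns the minimal points of `points` under the
#' coordinate-wise order (no other point is at least as small on both
#' coordinates and strictly smaller on one) using a randomized
#' divide-and-conquer algorithm: find one minimal point, discard its closed
#' upper quadrant, and recurse on the two open side rectangles.  Points whose
#' coordinates tie with a front point are all retained, so no tagged
#' (compound, model) pair is lost.  `pareto_front_brute()` is the exhaustive
#' all-pairs reference implementation used as an independent oracle.
#'
#' @inheritParams find_pareto_point
#'
#' @return A tibble of front rows (in input order) with class
#'   `"pareto_front"`, carrying attributes `initial` (the initial Pareto
#'   set), `bounds`, and `input` (the full point set, used by
#'   [autoplot.pareto_front()]).  The result is identical for every seed.
#' @examples
#' v <- data.frame(d = c(1, 2, 3, 4, 5), e = c(5, 3, 4, 1, 2))
#' pareto_front(v)
#' @export
pareto_front <- function(points, seed = NULL) {
  pts <- as_points(points)
  if (!is.null(seed)) withr::local_seed(seed)
  out <- pts[front_idx(pts$d, pts$e), ]
  init <- if (nrow(pts)) initial_pareto_set(pts) else list(points = pts, bounds = NULL)
  structure(
    out,
    initial = init$points,
    bounds = init$bounds,
    input = pts,
    class = c("pareto_front", class(out))
  )
}

#' @rdname pareto_front
#' @export
pareto_front_brute <- function(points) {
  pts <- as_points(points)
  pts[brute_idx(pts$d, pts$e), ]
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf(
    "# Pareto front: %d of %d points\n",
    nrow(x), nrow(attr(x, "input"))
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
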