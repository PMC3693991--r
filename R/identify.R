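# Model identification for a query chemical.
#
# The query and each table chemical define a distance coordinate (Tanimoto
# distance between fingerprints); each (chemical, model) pair contributes one
# point (d_i, e_im) to a single joint solution set V.  The Pareto front of V
# balances "similar chemical" against "well-predicted chemical"; the n-Pareto
# neighbourhood restricts the front to at most n points with d < tau, and the
# APMI / CPMI / DMS rules turn that neighbourhood into one selected model, so
# the procedure partitions chemical space among the collection's models.

#' Named method registry
#'
#' Maps the conventional method labels onto their neighbourhood settings:
#' `3-apmi`/`3-cpmi` use `n = 3, tau = 0.4`; `5-apmi`/`5-cpmi` use
#' `n = 5, tau = 0.7`; `10-cpmi` keeps every Pareto point (`n = 10`, no
#' distance cut-off); `dms` is the nearest-neighbour baseline.  Bare method
#' names (`apmi`, `cpmi`, `dms`, `oracle`) keep the `n`/`tau` given by the
#' caller.
#'
#' @param method Method label (see above).
#' @param n,tau Neighbourhood size and distance threshold used for bare
#'   method names; ignored (with a warning if supplied) for registry labels.
#' @return List with elements `base`, `n`, `tau`, `label`.
#' @export
resolve_method <- function(method, n = NULL, tau = NULL) {
  registry <- list(
    "3-apmi" = list(base = "apmi", n = 3, tau = 0.4),
    "5-apmi" = list(base = "apmi", n = 5, tau = 0.7),
    "3-cpmi" = list(base = "cpmi", n = 3, tau = 0.4),
    "5-cpmi" = list(base = "cpmi", n = 5, tau = 0.7),
    "10-cpmi" = list(base = "cpmi", n = 10, tau = Inf),
    "dms" = list(base = "dms", n = NA_integer_, tau = NA_real_)
  )
  if (!is.character(method) || length(method) != 1) {
    abort("`method` must be a single string")
  }
  method <- tolower(method)
  if (method %in% names(registry)) {
    if (!is.null(n) || !is.null(tau)) {
      warn(sprintf("method '%s' fixes n and tau; ignoring supplied values", method))
    }
    out <- registry[[method]]
    out$label <- method
    return(out)
  }
  if (!method %in% c("apmi", "cpmi", "dms", "oracle")) {
    abort(sprintf("unknown identification method '%s'", method))
  }
  n <- n %||% 3
  tau <- tau %||% 0.4
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != as.integer(n)) {
    abort("`n` must be a positive integer")
  }
  if (!is.numeric(tau) || length(tau) != 1 || !(tau > 0)) {
    abort("`tau` must be a positive distance threshold")
  }
  list(base = method, n = as.integer(n), tau = tau, label = method)
}

normalize_query <- function(query, width) {
  if (is.data.frame(query)) {
    if (nrow(query) != 1) abort("`query` data frame must have exactly one row")
    query <- as.list(query)
  }
  if (!is.list(query) || is.null(query$fingerprint)) {
    abort("`query` must be a list or one-row data frame with a `fingerprint`")
  }
  bits <- as_bits(query$fingerprint)
  if (length(bits) != width) {
    abort(sprintf(
      "query fingerprint has %d bits; the table uses %d", length(bits), width
    ))
  }
  if (sum(bits) == 0) abort("query fingerprint has no set bits")
  list(
    id = if (!is.null(query$id)) as.character(query$id) else NA_character_,
    bits = bits,
    predictions = query$predictions
  )
}

#' Convert a model table into the query's Pareto vector set
#'
#' For every chemical in the table (excluding any row whose id equals the
#' query's own, so held-out queries never see themselves) and every model
#' with a non-missing prediction, emits one tagged point with `d` the
#' Tanimoto distance from the query fingerprint and `e` the model's absolute
#' error on that chemical.
#'
#' @param tbl A [model_table()].
#' @param query A list or one-row data frame with `fingerprint` (bitstring or
#'   0/1 vector) and optionally `id`.
#' @return Tibble with columns `compound_id`, `model_id`, `d`, `e`.
#' @export
init_vectors <- function(tbl, query) {
  tbl <- validate_model_table(as_tibble(tbl))
  q <- normalize_query(query, nchar(tbl$fingerprint[1]))
  rows <- if (is.na(q$id)) seq_len(nrow(tbl)) else which(tbl$id != q$id)
  if (!length(rows)) {
    abort("excluding the query chemical leaves no chemicals in the table")
  }
  dq <- query_tanimoto_distance(q$bits, fp_matrix(tbl$fingerprint[rows]))
  err <- error_matrix(tbl)[rows, , drop = FALSE]
  mods <- model_names(tbl)
  out <- tibble(
    compound_id = rep(tbl$id[rows], times = length(mods)),
    model_id = rep(mods, each = length(rows)),
    d = rep(dq, times = length(mods)),
    e = as.vector(err)
  )
  out <- filter(out, !is.na(.data$e))
  if (nrow(out) == 0) abort("no (chemical, model) pair has a prediction")
  arrange(out, .data$compound_id, .data$model_id)
}

#' n-Pareto neighbourhood of a query
#'
#' Restricts a Pareto front to the points with distance coordinate strictly
#' below `tau`, sorts them (ascending `d`, ties by ascending `e`, compound
#' id, model id) and keeps the first `n`.  When no front point passes the
#' distance filter the single nearest front point is returned instead and
#' flagged, so that identification remains total over chemical space.
#'
#' @param front A [pareto_front()] (or tibble of tagged points on a front).
#' @param n Maximum neighbourhood size (positive integer).
#' @param tau Distance threshold in `(0, 1]`, or `Inf` to keep all points.
#' @return Tibble of at most `n` rows with attribute `fallback_used`.
#' @export
pareto_neighbourhood <- function(front, n = 3, tau = 0.4) {
  pts <- as_points(front)
  if (nrow(pts) == 0) abort("the Pareto front is empty")
  o <- order(pts$d, pts$e, pts$compound_id, pts$model_id)
  inside <- o[pts$d[o] < tau]
  fallback <- length(inside) == 0
  if (fallback) {
    warn(sprintf(
      "no Pareto point within tau = %g; falling back to the nearest point", tau
    ))
    inside <- o[1]
  }
  out <- pts[head(inside, n), ]
  structure(out, fallback_used = fallback,
            class = c("pareto_neighbourhood", class(out)))
}

#' Centroid of a Pareto neighbourhood
#'
#' @param nb A non-empty [pareto_neighbourhood()] (or tibble with `d`, `e`).
#' @return One-row tibble with the coordinate-wise means `d_c`, `e_c`.
#' @export
centroid <- function(nb) {
  if (!is.data.frame(nb) || nrow(nb) == 0) abort("the neighbourhood is empty")
  tibble(d_c = mean(nb$d), e_c = mean(nb$e))
}

# ---- selection cores (shared by identify() and loo_evaluate()) -------------
#
# All cores work on plain vectors/matrices for speed: dq (distances to the
# query for each candidate chemical), err (chemicals x models error matrix,
# NA = no prediction), ids (chemical ids), mods (model names in column
# order).  Tie-breaks are deterministic: APMI -> first model in column order;
# CPMI -> smaller e, then smaller d, then model order; DMS -> nearer
# chemical, then smaller best error, then id order.

core_identify <- function(dq, err, ids, mods, base, n, tau) {
  nc <- length(dq)
  m <- length(mods)
  if (base == "dms") {
    best <- apply(err, 1, min, na.rm = TRUE)
    cand <- which(dq == min(dq))
    if (length(cand) > 1) cand <- cand[best[cand] == min(best[cand])]
    if (length(cand) > 1) cand <- cand[order(ids[cand])]
    row <- cand[1]
    sel <- which.min(err[row, ])
    scores <- err[row, ]
    nb <- tibble(
      compound_id = rep(ids[row], m), model_id = mods,
      d = rep(dq[row], m), e = as.numeric(err[row, ])
    )
    nb <- filter(nb, !is.na(.data$e))
    return(list(
      selected = mods[sel], fallback = FALSE, neighbourhood = nb,
      scores = tibble(model = mods, score = as.numeric(scores)),
      centroid = NULL
    ))
  }

  d <- rep(dq, times = m)
  e <- as.vector(err)
  chem <- rep(seq_len(nc), times = m)
  mod <- rep(seq_len(m), each = nc)
  ok <- !is.na(e)
  d <- d[ok]; e <- e[ok]; chem <- chem[ok]; mod <- mod[ok]
  if (!length(d)) abort("no (chemical, model) pair has a prediction")

  fi <- front_idx(d, e)
  fd <- d[fi]; fe <- e[fi]; fchem <- chem[fi]; fmod <- mod[fi]
  o <- order(fd, fe, ids[fchem], fmod)
  inside <- o[fd[o] < tau]
  fallback <- length(inside) == 0
  if (fallback) inside <- o[1]
  nbi <- head(inside, n)

  nb <- tibble(
    compound_id = ids[fchem[nbi]], model_id = mods[fmod[nbi]],
    d = fd[nbi], e = fe[nbi]
  )

  if (base == "apmi") {
    chems <- unique(fchem[nbi])
    avg <- colMeans(err[chems, , drop = FALSE], na.rm = TRUE)
    sel <- which.min(avg) # ties -> first model in column order
    list(
      selected = mods[sel], fallback = fallback, neighbourhood = nb,
      scores = tibble(model = mods, score = as.numeric(avg)),
      centroid = NULL
    )
  } else { # cpmi
    dc <- mean(fd[nbi]); ec <- mean(fe[nbi])
    dist <- sqrt((fd[nbi] - dc)^2 + (fe[nbi] - ec)^2)
    pick <- nbi[order(dist, fe[nbi], fd[nbi], fmod[nbi])][1]
    per_model <- tapply(dist, mods[fmod[nbi]], min)
    list(
      selected = mods[fmod[pick]], fallback = fallback, neighbourhood = nb,
      scores = tibble(
        model = names(per_model), score = as.numeric(per_model)
      ),
      centroid = tibble(d_c = dc, e_c = ec)
    )
  }
}

#' Identify the most reliable model for a query chemical
#'
#' Runs the full identification pipeline: build the Pareto vector set with
#' [init_vectors()], compute its front, take the n-Pareto neighbourhood, and
#' select one model by the requested rule.  `apmi` averages each model's
#' error over the distinct chemicals represented in the neighbourhood (full
#' error rows from the table) and picks the smallest average; `cpmi` picks
#' the model tagged to the neighbourhood point closest (Euclidean) to the
#' neighbourhood centroid; `dms` ignores the front and returns the best
#' model for the single nearest chemical.  When the front has a single
#' point, all methods agree on that point's model.
#'
#' @inheritParams init_vectors
#' @param method A registry label (`"3-apmi"`, `"5-apmi"`, `"3-cpmi"`,
#'   `"5-cpmi"`, `"10-cpmi"`, `"dms"`) or a bare method (`"apmi"`, `"cpmi"`,
#'   `"dms"`) combined with `n` and `tau`.
#' @param n,tau Neighbourhood parameters for bare methods (defaults 3, 0.4).
#' @param seed Optional seed for the randomized front search (the selected
#'   model never depends on it).
#'
#' @return An object of class `"model_identification"`: a list with
#'   `query_id`, `method`, `selected_model`, `neighbourhood` (tibble),
#'   `scores` (per-model tibble: average errors for APMI, centroid distances
#'   for CPMI, nearest-neighbour errors for DMS), `centroid` (CPMI only),
#'   `fallback_used`, and `prediction` (the selected model's prediction for
#'   the query when `query$predictions` supplies one per model, else `NA`).
#'   [tidy()] returns the score table, [glance()] a one-row summary.
#' @examples
#' fix <- worked_example_fixtures()
#' identify(fix$A$table, fix$A$query, "3-apmi")$selected_model # "NPN"
#' @export
identify <- function(tbl, query, method = "3-apmi", n = NULL, tau = NULL,
                     seed = NULL) {
  spec <- resolve_method(method, n, tau)
  if (spec$base == "oracle") {
    abort("method 'oracle' is only available inside loo_evaluate()")
  }
  tbl <- validate_model_table(as_tibble(tbl))
  q <- normalize_query(query, nchar(tbl$fingerprint[1]))
  rows <- if (is.na(q$id)) seq_len(nrow(tbl)) else which(tbl$id != q$id)
  if (!length(rows)) {
    abort("excluding the query chemical leaves no chemicals in the table")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  dq <- query_tanimoto_distance(q$bits, fp_matrix(tbl$fingerprint[rows]))
  res <- core_identify(
    dq, error_matrix(tbl)[rows, , drop = FALSE], tbl$id[rows],
    model_names(tbl), spec$base, spec$n, spec$tau
  )
  pred <- NA_real_
  if (!is.null(q$predictions) && res$selected %in% names(q$predictions)) {
    pred <- as.numeric(q$predictions[[res$selected]])
  }
  structure(
    list(
      query_id = q$id,
      method = spec$label,
      n = spec$n,
      tau = spec$tau,
      selected_model = res$selected,
      neighbourhood = res$neighbourhood,
      scores = res$scores,
      centroid = res$centroid,
      fallback_used = res$fallback,
      prediction = pred
    ),
    class = "model_identification"
  )
}

#' @export
print.model_identification <- function(x, ...) {
  cat(sprintf(
    "<model_identification> query %s | method %s -> %s%s\n",
    x$query_id, x$method, x$selected_model,
    if (x$fallback_used) " (neighbourhood fallback)" else ""
  ))
  cat("Neighbourhood:\n")
  print(x$neighbourhood, ...)
  cat("Scores:\n")
  print(x$scores, ...)
  invisible(x)
}
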