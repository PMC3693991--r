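test_that("init_vectors expands (chemical, model) pairs with hand-checked values", {
  # single chemical at distance 0.4 from the query, two models
  chems <- tibble::tibble(
    id = "c1", fingerprint = "1110000000", activity = 0,
    pred_M1 = 0.1, pred_M2 = -0.9
  )
  tbl <- model_table(chems)
  q <- list(id = "q", fingerprint = "1111100000") # common 3, union 5 -> d = 0.4
  v <- init_vectors(tbl, q)
  expect_equal(nrow(v), 2)
  expect_equal(v$d, c(0.4, 0.4))
  expect_equal(v$e, c(0.1, 0.9))

  # identical fingerprint -> d = 0; query's own row excluded
  chems2 <- dplyr::bind_rows(
    chems,
    tibble::tibble(id = "q", fingerprint = "1111100000", activity = 0,
                   pred_M1 = 5, pred_M2 = 5),
    tibble::tibble(id = "twin", fingerprint = "1111100000", activity = 1,
                   pred_M1 = 1.2, pred_M2 = 0.5)
  )
  v2 <- init_vectors(model_table(chems2), q)
  expect_false("q" %in% v2$compound_id)
  expect_equal(v2$d[v2$compound_id == "twin"], c(0, 0))
  expect_equal(sort(v2$e[v2$compound_id == "twin"]), c(0.2, 0.5))

  # 3 chemicals x 2 models -> 6 tagged points
  v3 <- init_vectors(small_logp_table(), list(fingerprint = "11000011"))
  expect_equal(nrow(v3), 6)
  expect_equal(
    v3$e,
    model_errors(small_logp_table())$error[order(
      model_errors(small_logp_table())$id,
      model_errors(small_logp_table())$model
    )],
    tolerance = 1e-12
  )

  only_q <- model_table(chems2[2, ])
  expect_error(init_vectors(only_q, q), "leaves no chemicals")
})

test_that("the Pareto neighbourhood filters, sorts, truncates, and falls back", {
  # a three-point neighbourhood: all within tau = 0.4
  front <- tibble::tibble(
    compound_id = c("m", "d", "c"), model_id = c("NPN", "NPN", "PN"),
    d = c(0.33, 0.36, 0.30), e = c(0.28, 0.08, 0.61)
  )
  nb <- pareto_neighbourhood(front, n = 3, tau = 0.4)
  expect_equal(nrow(nb), 3)
  expect_equal(nb$d, c(0.30, 0.33, 0.36)) # ascending distance
  expect_false(attr(nb, "fallback_used"))

  # all beyond tau: fall back to the single nearest point
  far <- dplyr::mutate(front, d = d + 0.5)
  expect_warning(nbf <- pareto_neighbourhood(far, n = 3, tau = 0.4), "falling back")
  expect_equal(nrow(nbf), 1)
  expect_equal(nbf$d, 0.80)
  expect_true(attr(nbf, "fallback_used"))

  # five candidates under tau, n = 3 -> the three nearest
  five <- tibble::tibble(
    compound_id = letters[1:5], model_id = "M1",
    d = c(0.10, 0.05, 0.30, 0.20, 0.15), e = c(5, 6, 1, 3, 4)
  )
  nb5 <- pareto_neighbourhood(five, n = 3, tau = 0.4)
  expect_equal(nb5$compound_id, c("b", "a", "e"))

  expect_error(
    pareto_neighbourhood(tibble::tibble(d = numeric(), e = numeric())),
    "empty"
  )
})

test_that("centroid is the coordinate-wise mean", {
  nb <- tibble::tibble(d = c(0, 2), e = c(0, 2))
  expect_equal(centroid(nb), tibble::tibble(d_c = 1, e_c = 1))
  one <- tibble::tibble(d = 0.3, e = 0.7)
  expect_equal(centroid(one), tibble::tibble(d_c = 0.3, e_c = 0.7))
  three <- tibble::tibble(d = c(0.1, 0.2, 0.3), e = c(0.3, 0.1, 0.2))
  expect_equal(centroid(three), tibble::tibble(d_c = 0.2, e_c = 0.2))
  expect_error(centroid(tibble::tibble(d = numeric(), e = numeric())), "empty")
})

test_that("APMI reproduces both bundled worked examples", {
  fix <- worked_example_fixtures()

  # the averaging step alone
  a_step <- apmi_average(fix$A$neighbours[c("PN", "NPN")])
  expect_equal(a_step$selected, "NPN")
  expect_equal(unname(a_step$means), c(mean(c(0.37, 0.54, 0.61)), 0.50))
  b_step <- apmi_average(fix$B$neighbours[c("PN", "NPN")])
  expect_equal(b_step$selected, "PN")

  # end to end through fingerprints, front and neighbourhood
  a <- identify(fix$A$table, fix$A$query, "3-apmi")
  expect_equal(a$selected_model, "NPN")
  expect_equal(sort(a$neighbourhood$compound_id), sort(fix$A$table$id))
  expect_equal(
    a$scores$score[a$scores$model == "NPN"], 0.50, tolerance = 1e-12
  )
  b <- identify(fix$B$table, fix$B$query, "3-apmi")
  expect_equal(b$selected_model, "PN")

  # single-chemical neighbourhood: the model with that chemical's best error
  one <- identify(single_front_table(), single_front_query(), "apmi")
  expect_equal(one$selected_model, "M1")
})

test_that("CPMI picks the point nearest the centroid with documented tie-breaks", {
  tbl <- single_front_table()
  q <- single_front_query()
  expect_equal(identify(tbl, q, "cpmi")$selected_model, "M1")

  # two points, exactly equidistant from the midpoint (binary-exact
  # coordinates); tie -> lower-error point
  two <- tibble::tibble(
    compound_id = c("a", "b"), model_id = c("MA", "MB"),
    d = c(0.25, 0.75), e = c(0.75, 0.25)
  )
  cen <- centroid(two)
  dist <- sqrt((two$d - cen$d_c)^2 + (two$e - cen$e_c)^2)
  expect_identical(dist[1], dist[2])

  chems <- tibble::tibble(
    id = c("a", "b"),
    fingerprint = c("1110", "1000"),
    activity = 0, pred_MA = c(0.75, 9), pred_MB = c(9, 0.25)
  )
  # distances to q = 1111: a -> 0.25 (3/4 sim), b -> 0.75 (1/4 sim); the
  # front is {(0.25, 0.75, MA), (0.75, 0.25, MB)}, both within tau = 0.9
  res <- identify(model_table(chems), list(fingerprint = "1111"),
                  "cpmi", n = 3, tau = 0.9)
  expect_equal(res$selected_model, "MB") # tie on distance -> smaller e wins

  # three points with distinct centroid distances: verify by brute force
  front3 <- tibble::tibble(
    compound_id = c("x", "y", "z"), model_id = c("M1", "M2", "M1"),
    d = c(0.05, 0.15, 0.35), e = c(0.9, 0.25, 0.05)
  )
  cen3 <- centroid(front3)
  d3 <- sqrt((front3$d - cen3$d_c)^2 + (front3$e - cen3$e_c)^2)
  expect_equal(which.min(d3), 2)
})

test_that("DMS selects the best model of the nearest neighbour", {
  chems <- tibble::tibble(
    id = c("near", "far"),
    fingerprint = c("1111111110", "1110000000"),
    activity = 0,
    pred_M1 = c(0.3, 0.01), pred_M2 = c(0.1, 0.9)
  )
  tbl <- model_table(chems)
  res <- identify(tbl, list(fingerprint = "1111111111"), "dms")
  expect_equal(res$selected_model, "M2") # near's smaller error, not far's

  # equal distances: the chemical with the smaller best error decides
  tie <- tibble::tibble(
    id = c("t1", "t2"),
    fingerprint = c("1110", "1101"),
    activity = 0,
    pred_M1 = c(0.2, 0.5), pred_M2 = c(0.8, 0.05)
  )
  res2 <- identify(model_table(tie), list(fingerprint = "1111"), "dms")
  expect_equal(res2$selected_model, "M2")

  # single-chemical table
  solo <- model_table(chems[1, ])
  expect_equal(
    identify(solo, list(fingerprint = "1111111111"), "dms")$selected_model,
    "M2"
  )
})

test_that("identification is a total, deterministic partition of methods", {
  expect_error(identify(single_front_table(), single_front_query(), "bogus"),
               "unknown identification method")

  # |front| = 1: every method agrees with the front point's own tag
  tbl <- single_front_table()
  q <- single_front_query()
  v <- init_vectors(tbl, q)
  front <- pareto_front(v, seed = 3)
  expect_equal(nrow(front), 1)
  for (m in c("apmi", "cpmi", "dms")) {
    expect_equal(identify(tbl, q, m)$selected_model, front$model_id)
  }

  # every random query gets exactly one model, independent of the seed
  withr::local_seed(31)
  gen <- generate_dataset(n_chemicals = 40, n_bits = 64, n_clusters = 2,
                          n_models = 2, seed = 8)
  for (i in 1:10) {
    qfp <- paste(rbinom(64, 1, 0.5), collapse = "")
    if (!grepl("1", qfp)) qfp <- paste0("1", substr(qfp, 2, 64))
    sel <- vapply(
      c(2, 77),
      function(s) identify(gen$table, list(fingerprint = qfp), "3-apmi",
                           seed = s)$selected_model,
      character(1)
    )
    expect_equal(sel[1], sel[2])
    expect_true(sel[1] %in% model_names(gen$table))
  }
})

test_that("enlarging tau never shrinks the neighbourhood", {
  withr::local_seed(17)
  for (i in 1:20) {
    front <- pareto_front(random_points(sample(5:50, 1)))
    sizes <- vapply(
      c(0.2, 0.4, 0.8, Inf),
      function(tau) {
        nb <- suppressWarnings(
          pareto_neighbourhood(front, n = .Machine$integer.max, tau = tau)
        )
        if (attr(nb, "fallback_used")) 0L else nrow(nb)
      },
      integer(1)
    )
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("the method registry fixes the published n and tau settings", {
  expect_equal(resolve_method("3-apmi")[c("base", "n", "tau")],
               list(base = "apmi", n = 3, tau = 0.4))
  expect_equal(resolve_method("5-apmi")[c("n", "tau")], list(n = 5, tau = 0.7))
  expect_equal(resolve_method("3-cpmi")[c("base", "n", "tau")],
               list(base = "cpmi", n = 3, tau = 0.4))
  expect_equal(resolve_method("5-cpmi")[c("n", "tau")], list(n = 5, tau = 0.7))
  expect_equal(resolve_method("10-cpmi")[c("n", "tau")], list(n = 10, tau = Inf))
  expect_warning(resolve_method("3-apmi", n = 7), "fixes n and tau")
  expect_error(resolve_method("apmi", n = 0), "positive integer")
  expect_error(resolve_method("apmi", tau = -1), "positive distance")
})
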