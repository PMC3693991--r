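# Shared fixtures, all generated in code.

# Random tagged point sets with coordinate ties and duplicate points: with
# probability 1/2 coordinates are drawn from a coarse decimal grid.
random_points <- function(n, grid = runif(1) < 0.5) {
  if (grid) {
    d <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    e <- sample(seq(0, 2, by = 0.2), n, replace = TRUE)
  } else {
    d <- runif(n)
    e <- runif(n, 0, 2)
  }
  tibble::tibble(
    compound_id = sprintf("c%03d", seq_len(n)),
    model_id = sample(c("M1", "M2"), n, replace = TRUE),
    d = d, e = e
  )
}

point_key <- function(pts) {
  sort(paste(pts$compound_id, pts$model_id, pts$d, pts$e, sep = "|"))
}

# Three chemicals with logP plus the bundled PN/NPN providers.
small_logp_table <- function() {
  chems <- tibble::tibble(
    id = c("a", "b", "c"),
    fingerprint = c("11110000", "11001100", "00111100"),
    activity = c(-0.5, 0.3, 1.2),
    logp = c(0.8, 1.6, 3.1)
  )
  model_table(chems, qsar_igc50_models())
}

# A table in which one chemical dominates every Pareto comparison for the
# given query (distance and both errors smallest), forcing |front| = 1.
single_front_table <- function() {
  chems <- tibble::tibble(
    id = c("near", "far1", "far2"),
    fingerprint = c("11111100", "11000011", "10100011"),
    activity = c(0, 0, 0),
    pred_M1 = c(0.01, 0.60, 0.70),
    pred_M2 = c(0.50, 0.80, 0.90)
  )
  model_table(chems)
}

single_front_query <- function() list(id = "q", fingerprint = "11111000")
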