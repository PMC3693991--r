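# Synthetic clustered chemical spaces.
#
# The generator emulates the structure the identification method assumes:
# chemicals fall into structural clusters (fingerprints are noisy copies of a
# cluster prototype), activity follows a cluster-specific affine law of a
# latent descriptor, and the model collection contains one specialist per
# cluster -- exact (up to measurement noise) on its own cluster and biased
# elsewhere.  Ground-truth cluster labels are returned separately and never
# written into the model-table CSV, so identification cannot see them.

#' Generate a clustered synthetic model table
#'
#' Draws `n_clusters` random prototype fingerprints; each chemical copies its
#' cluster's prototype with independent bit flips (probability `flip_prob`).
#' A latent descriptor is uniform on `descriptor_range`; the measured
#' activity is `slope_c * x + intercept_c + N(0, noise_sd)` for cluster
#' `c`-specific coefficients (slopes `0.5 + 0.3 (c-1)`, intercepts
#' `-2 + 1.2 (c-1)`, spreads comparable to published single-descriptor
#' narcosis models).  Model `k` predicts the chemical's true affine mean, plus
#' `foreign_bias` when the chemical is outside cluster `k` -- each model is a
#' reliable specialist on exactly one structural cluster.  Clusters are
#' assigned in (shuffled) balanced fashion and recycled when
#' `n_models > n_clusters`.
#'
#' @param n_chemicals,n_bits,n_clusters,n_models Dataset dimensions.
#' @param flip_prob Per-bit flip probability in `(0, 0.5)`.
#' @param noise_sd Standard deviation of the activity measurement noise.
#' @param foreign_bias Systematic error a model incurs off its own cluster.
#' @param descriptor_range Range of the latent descriptor.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return List with `table` (a [model_table()] with models `M1..Mk`) and
#'   `truth` (tibble: `id`, `cluster`, `descriptor`).
#' @examples
#' gen <- generate_dataset(n_chemicals = 30, n_bits = 64, seed = 1)
#' gen$table
#' @export
generate_dataset <- function(n_chemicals = 500, n_bits = 256, n_clusters = 4,
                             n_models = 4, flip_prob = 0.05, noise_sd = 0.3,
                             foreign_bias = 1.0, descriptor_range = c(0, 5),
                             seed = 42) {
  stopifnot(
    n_chemicals >= 1, n_bits >= 8, n_clusters >= 1, n_models >= 2,
    flip_prob > 0, flip_prob < 0.5, noise_sd >= 0, foreign_bias >= 0,
    length(descriptor_range) == 2, descriptor_range[1] < descriptor_range[2]
  )
  withr::local_seed(as.integer(seed))

  protos <- matrix(
    rbinom(n_clusters * n_bits, 1, 0.5), nrow = n_clusters
  )
  while (any(rowSums(protos) == 0)) {
    warn("regenerating an all-zero cluster prototype")
    i <- which(rowSums(protos) == 0)[1]
    protos[i, ] <- rbinom(n_bits, 1, 0.5)
  }

  cluster <- sample(rep_len(seq_len(n_clusters), n_chemicals))
  flips <- matrix(
    rbinom(n_chemicals * n_bits, 1, flip_prob), nrow = n_chemicals
  )
  fp <- (protos[cluster, , drop = FALSE] + flips) %% 2
  zero <- which(rowSums(fp) == 0)
  for (i in zero) { # vanishingly rare; keep similarity well-defined
    warn(sprintf("chemical %d drew an all-zero fingerprint; setting one bit", i))
    fp[i, sample.int(n_bits, 1)] <- 1L
  }

  slopes <- 0.5 + 0.3 * (seq_len(n_clusters) - 1)
  intercepts <- -2 + 1.2 * (seq_len(n_clusters) - 1)
  x <- runif(n_chemicals, descriptor_range[1], descriptor_range[2])
  mu <- slopes[cluster] * x + intercepts[cluster]
  activity <- mu + rnorm(n_chemicals, 0, noise_sd)

  chems <- tibble(
    id = sprintf("CHEM%04d", seq_len(n_chemicals)),
    fingerprint = apply(fp, 1, paste0, collapse = ""),
    activity = activity
  )
  model_cluster <- rep_len(seq_len(n_clusters), n_models)
  for (k in seq_len(n_models)) {
    chems[[sprintf("pred_M%d", k)]] <-
      mu + foreign_bias * (cluster != model_cluster[k])
  }
  list(
    table = validate_model_table(chems),
    truth = tibble(
      id = chems$id, cluster = cluster, descriptor = x
    )
  )
}

#' Worked neighbourhood fixtures for the two narcosis models
#'
#' Two ready-made 3-Pareto-neighbourhood examples over the PN/NPN collection,
#' each in two forms: the neighbourhood error table alone (`neighbours`:
#' chemical name, distance to the query, PN and NPN absolute errors, with the
#' expected selection), and a full end-to-end setting (`table` + `query`)
#' whose fingerprints are engineered so the Tanimoto distances and the
#' resulting front reproduce the same neighbourhood.  Fixture `A`
#' (3-Phenyl-1-propanol's neighbourhood) selects `NPN` by average error;
#' fixture `B` (Benzylamine's) selects `PN`.
#'
#' @return List of two fixtures `A` and `B`, each with elements
#'   `neighbours`, `expected`, `table`, `query`.
#' @export
worked_example_fixtures <- function() {
  bits <- function(on) paste(as.integer(seq_len(50) %in% on), collapse = "")
  q <- bits(1:25)

  # Distances from q: shared-bit counts give 0.30, 1/3 (~0.33) and 0.36.
  a_chems <- tibble(
    id = c("4-Chloro-3-methylphenol", "Methylbenzene", "4-Dimethylbenzene"),
    fingerprint = c(bits(c(1:21, 26:30)), bits(c(1:20, 31:35)), bits(1:16)),
    activity = 0,
    pred_PN = c(0.61, 0.37, 0.54),
    pred_NPN = c(1.14, 0.28, 0.08)
  )
  a_nb <- tibble(
    name = c("Methylbenzene", "4-Dimethylbenzene", "4-Chloro-3-methylphenol"),
    distance = c(0.33, 0.36, 0.30),
    PN = c(0.37, 0.54, 0.61),
    NPN = c(0.28, 0.08, 1.14)
  )

  # Distances from q: 0.08 and 25/28 similarity (~0.11).
  b_chems <- tibble(
    id = c("2-Chloroaniline", "(+/-)-1,2-Diphenyl-2-propanol"),
    fingerprint = c(bits(1:23), bits(1:28)),
    activity = 0,
    pred_PN = c(0.30, 0.041),
    pred_NPN = c(0.38, 0.59)
  )
  b_nb <- tibble(
    name = b_chems$id,
    distance = c(0.08, 0.11),
    PN = c(0.30, 0.041),
    NPN = c(0.38, 0.59)
  )

  list(
    A = list(
      neighbours = a_nb, expected = "NPN",
      table = validate_model_table(a_chems),
      query = list(id = "3-Phenyl-1-propanol", fingerprint = q)
    ),
    B = list(
      neighbours = b_nb, expected = "PN",
      table = validate_model_table(b_chems),
      query = list(id = "Benzylamine", fingerprint = q)
    )
  )
}

#' Select a model by averaging neighbourhood errors
#'
#' The averaging step of the APMI rule in isolation: given per-chemical model
#' errors for the chemicals of a Pareto neighbourhood, averages each error
#' column and returns the model with the smallest mean (ties to the first
#' column).
#'
#' @param errors Data frame with one numeric error column per model (any
#'   non-numeric columns are ignored).
#' @return List with `selected` and `means` (named numeric).
#' @examples
#' apmi_average(worked_example_fixtures()$A$neighbours[c("PN", "NPN")])
#' @export
apmi_average <- function(errors) {
  errors <- as_tibble(errors)
  num <- errors[vapply(errors, is.numeric, logical(1))]
  if (ncol(num) < 2) abort("need at least two numeric error columns")
  means <- colMeans(as.matrix(num))
  list(selected = names(means)[which.min(means)], means = means)
}
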