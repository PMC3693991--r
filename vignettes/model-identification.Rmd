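---
title: "Pareto-optimal model identification for QSAR model collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto-optimal model identification for QSAR model collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretoqsar)
```

## The problem

Public repositories hold many QSAR models for the same endpoint, each
trained on its own chemical series and reliable only inside its own
applicability domain. Given a new (query) chemical and a collection of
such models, which one should make the prediction? No single model wins
everywhere, and models from different sources cannot be compared by their
published validation statistics because those were computed on different
datasets.

`paretoqsar` answers the question with the data that *is* shared across
models: a table of chemicals with measured activities and every model's
prediction for each of them. For a query compound $q$, each
(chemical $i$, model $m$) pair becomes a point

$$(d_i, \; e_{im}) = \bigl(1 - S_T(q, x_i), \; |y_i - \hat y_m(x_i)|\bigr),$$

where $S_T$ is the Tanimoto coefficient on binary fingerprints and
$e_{im}$ the model's absolute error on chemical $i$. A good witness for a
model is a chemical that is *both* similar to the query and well
predicted — a bi-criteria problem whose undominated trade-offs are exactly
the 2D Pareto-minimal points of the set.

## Pareto front machinery

A point $v$ is dominated by $w$ when $w$ is coordinate-wise no larger;
the front is the set of points not strictly dominated downward by any
other. Two properties special to two dimensions drive the algorithm:

* the *initial Pareto set* (the minimisers of each coordinate, resolved
  on the other coordinate) has at most two distinct coordinate pairs, and
  both belong to the front;
* a point is incomparable with both initial members exactly when it lies
  in the open rectangle spanned by their coordinates.

`pareto_front()` therefore finds one minimal point by random descent
(`find_pareto_point()`: start anywhere, repeatedly move to any point
strictly below), emits it, discards its upper quadrant, and repeats on
the two open side rectangles. The recursion is implemented with an
explicit work stack because the front can be as large as the input. The
result never depends on the seed — only the internal search order does —
and the package ships `pareto_front_brute()`, an exhaustive all-pairs
scan, purely as an independent oracle for the tests.

Numerical choices: comparisons are **exact** (no tolerance). Coordinates
here are ratios of small integers (bit counts) and short decimals;
an epsilon would silently merge distinct front points. Points whose
coordinates tie exactly are all kept, so no (compound, model) tag is
lost. Empty input yields an empty front.

## From front to model: n-Pareto neighbourhoods

The front still mixes witnesses for different models, and fingerprint
similarity correlates only loosely with activity similarity (see
`similarity_activity_table()`, which counts, for all pairs in a dataset,
how often "structurally similar" co-occurs with "similar activity").
Identification therefore restricts attention to the *n-Pareto
neighbourhood*: the at most `n` front points with distance strictly
below `tau`, sorted by distance (ties: error, compound id, model id).
If no front point passes the filter the nearest one is used and flagged
(`fallback_used`), because a partitioning model must assign *some* model
to every query.

Three selection rules are provided:

* **APMI** (average Pareto model identification): take the distinct
  chemicals represented in the neighbourhood, average each model's error
  over those chemicals using the full error rows of the table, select
  the smallest mean (ties: first model in column order).
* **CPMI** (centroid Pareto model identification): compute the
  neighbourhood centroid (coordinate-wise mean) and select the model
  tagged to the point with the smallest Euclidean distance to it
  (ties: smaller error, then smaller distance, then model order).
* **DMS** (double-min-score baseline): ignore the front; take the single
  nearest chemical (ties: smaller best error, then id) and its best
  model.

When the front is a single point, all rules return that point's tag.
The named settings `3-apmi`/`3-cpmi` (`n = 3, tau = 0.4`),
`5-apmi`/`5-cpmi` (`n = 5, tau = 0.7`) and `10-cpmi` (all front points)
follow the conventional choices for these methods; `tau` trades off how
dissimilar a well-predicted chemical may be before its evidence is
discarded, and suits fingerprints whose typical within-series distances
are well below 0.4.

Design choices worth making explicit, since the procedure leaves them
open:

* The vector set $V$ is built **jointly** over all (chemical, model)
  pairs — one front for the whole collection, not one per model — so the
  neighbourhood can weigh models against each other on the same
  chemicals.
* The query's own row (matched by id) is excluded when building $V$,
  which is what makes leave-one-out evaluation honest.
* Neighbourhood truncation keeps the *n* nearest-by-distance points, and
  the `d < tau` filter is strict.
* Missing predictions make a (chemical, model) pair ineligible as a
  point rather than being imputed; APMI averages skip them.
* All tie-breaks are deterministic and documented above, so every method
  is seed-independent end to end.

## Evaluation

`oracle_labels()` assigns each chemical the model with the smallest
absolute error — the a-priori best selector, an upper bound for every
method. `loo_evaluate()` holds out each chemical, identifies a model
from the rest, and reports:

* a classification block against the oracle labels (correct counts,
  false positives/negatives for a designated positive class, accuracy);
* a regression block for the *partitioning model* — the selected model's
  stored prediction per held-out chemical — with $R^2$ (squared Pearson
  correlation), RSE, $Q^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$
  (with $\bar y$ over the evaluated set), MAE and RMSE.

RSE is defined as the residual standard error of the simple linear
regression of observed on predicted. This affine-invariant reading is
deliberate: two models that are affine functions of the same descriptor
(such as the bundled PN and NPN narcosis models, $0.62\,\log P - 1.00$
and $0.83\,\log P - 2.07$) then share both $R^2$ and RSE while differing
in $Q^2$, MAE and RMSE — a property the test suite asserts. $Q^2$ uses
the PRESS form above because no alternative is fixed by the procedure;
the choice is recorded here and in the report metadata. Degenerate
inputs are refused rather than patched: constant observed vectors (no
correlation defined), fewer than three pairs, all-zero fingerprints.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds the structure the method assumes:
fingerprints are noisy copies (bit-flip probability `flip_prob`) of
random cluster prototypes; activity follows a cluster-specific affine
law of a latent descriptor (uniform on $[0, 5]$; slopes
$0.5 + 0.3(c-1)$, intercepts $-2 + 1.2(c-1)$, spreads comparable to
published single-descriptor narcosis models) plus Gaussian noise
(`noise_sd`); and model $k$ predicts the true affine mean on cluster $k$
but incurs a systematic `foreign_bias` elsewhere. Defaults
(`n_chemicals = 500`, `n_bits = 256`, 4 clusters and models,
`flip_prob = 0.05`, `noise_sd = 0.3`, `foreign_bias = 1`, `seed = 42`)
are the package's moderate-noise study condition; the low-noise
condition used for the accuracy benchmark is `flip_prob = 0.02`,
`noise_sd = 0.05`, `foreign_bias = 1`. Ground-truth cluster labels are
returned in a separate tibble and never written into the model-table
CSV.

This emulates cluster structure, specialist models and the
similar-structure/similar-activity hypothesis. It does **not** emulate
real fingerprint bit correlations, activity cliffs, heteroscedastic
assay noise, or model collections whose domains overlap irregularly.
Passing tests on synthetic data therefore demonstrate that the machinery
is correct and that identification beats any fixed model *when the
assumed structure is present* — not that it will on any particular
laboratory dataset.

## Problem sizes and reproducibility

The shipped checks use: 1000 random point sets of size 1–500 (with
deliberate coordinate ties) for front/oracle equivalence; 200 instances
for the initial-set rectangle properties; the 500-chemical synthetic
benchmark above for leave-one-out accuracy and $Q^2$ comparisons. These
sizes give stable statistics at interactive runtimes. All randomness
flows through explicit seeds (`withr::local_seed`); generator output is
byte-identical for a fixed seed, and identification results are
seed-invariant by construction.

## Known limitations

* Two criteria only: the front algorithm and the rectangle property are
  2D-specific; $K > 2$ objectives are out of scope.
* Fingerprints are consumed precomputed. Fingerprint software versions
  differ enough that recomputation is a data-preparation step, not a
  core concern; any toolkit that emits bitstrings can feed the CSV
  dialect.
* Selection quality degrades gracefully but noticeably as `tau` admits
  chemicals whose similarity no longer predicts activity similarity —
  the pairwise count table is the diagnostic to run first on new data.
* The bundled PN/NPN models reproduce their published predictions only
  when given the same logP inputs; logP is treated as an input column.
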