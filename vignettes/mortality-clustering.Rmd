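---
title: "Clustering mortality records with SOM-Ward: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering mortality records with SOM-Ward: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind **somward**, the
choices that were genuinely open when designing it, and what the synthetic
benchmark does and does not demonstrate.

## The data model

A multiple-cause-of-death (MCOD) record is one death certificate: up to 20
entity-axis ICD-10 condition codes (the health conditions present at
death), one underlying-cause code, and demographic attributes (age, sex,
race, education, marital status, resident status, place and manner of
death). Condition codes are aggregated into disease categories by
longest-prefix rules (`category_map()`); the *set* of distinct categories
on a record — duplicates collapse, because two codes in the same category
are not different health conditions — is the clustering feature, encoded as
a binary indicator vector. A record is *multimorbid* when it carries two or
more different categories, and records with no condition at all are omitted
before analysis (`filter_usable()` keeps the bookkeeping: usable + omitted
= parsed − malformed).

Two conventions are worth making explicit because published mortality
tables force them:

* **Denominators.** Percentages for demographic categoricals use the
  *non-missing* denominator (the sum of the printed level counts), which is
  the only convention under which the printed counts and percentages of
  large mortality tables are mutually consistent — most visibly for manner
  of death, where roughly a fifth of records carry no manner. Condition
  prevalences and the multimorbidity share instead use the full group size:
  every usable record has a well-defined condition set.
* **Rounding.** Half-up (`round_half_up()`), two decimals in tables, one
  decimal in prose-style figures. Base R's round-half-to-even would flip
  boundary cases.

## Batch SOM

`som_train()` implements the batch Kohonen map on a rectangular lattice
with Euclidean grid distance:

* assignment: BMU = nearest codebook vector, ties to the lowest node index;
* update: every node becomes the Gaussian-kernel-weighted mean of all
  sample rows, `h(d, σ) = exp(−d²/2σ²)`, σ interpolated linearly from
  `sigma_start` (default half the longer grid side, in grid units) to
  `sigma_end` (default 0.5); nodes receiving zero kernel mass keep their
  previous vector.

The batch variant was chosen over online training because it is
deterministic given the seed and is the standard industrial variant for the
train-on-a-sample / map-everything workflow. Each update is a convex
combination of sample rows, so codebook entries stay inside the data's
column ranges — in `[0, 1]` for indicator data — and in the zero-radius
limit one batch epoch is exactly one Lloyd (k-means) centroid update; both
properties are asserted in the test suite. Initialization is `pca_plane`
(codebook laid out linearly on the first two principal axes, centered on
the data mean; degenerates to the mean for a 1×1 grid, and falls back to a
constant plane with a warning on zero-variance data) or seeded `random`
row sampling. Indicator columns are used unscaled; a per-column variance
scaling is deliberately *not* applied by default because prevalence itself
is the signal of interest for binary disease indicators.

The hexagonal lattice common in some SOM software is deliberately omitted:
the rectangular lattice with 4-connectivity keeps adjacency, edge counts
and the contiguity constraint elementary, and nothing downstream depends on
the lattice type.

## SOM-Ward

`som_ward_cluster()` agglomerates map nodes under Ward's minimum-variance
criterion with merge cost `(w_a w_b/(w_a+w_b))·||μ_a − μ_b||²` — exactly
the increase in total weighted within-cluster sum of squares — restricted
to lattice-adjacent clusters. Design points:

* **Weights are mapped record counts**, not one per node: the clusters are
  clusters of people, and profiling runs on the entire mapped data set, not
  the training sample.
* **Empty nodes** (no mapped records) are pre-attached with zero weight to
  the owner of their nearest non-empty lattice node, walking outward over
  lattice edges so attachment never disconnects a region. Zero weight means
  they cannot distort any Ward cost.
* **Ties** (equal merge costs, e.g. on symmetric synthetic maps) resolve to
  the lexicographically smallest pair of lowest member-node indices, making
  runs bit-reproducible.
* Merge costs of the constrained algorithm are **not guaranteed
  monotone** — a contiguity constraint can force a cheap merge late — so no
  monotonicity is asserted; instead the suite checks the exact conservation
  identity: the accepted merge costs sum to the final partition's weighted
  SSE (node singletons start at zero).
* Final labels are 1..k by decreasing record weight, so "cluster 1" is
  always the largest.

`choose_k()` suggests a cluster count via the largest relative jump in
successive merge costs over k in 2..30 (ties to the smallest k). This
selection rule is an explicit convention of this package — published
SOM-Ward analyses of national mortality data report a sixteen-cluster
solution without stating how the count was selected, and the bundled
configurations therefore default to a user-chosen `k = 16`; `choose_k()`
is a diagnostic, and an explicit `k` always overrides it.

The profiling t-test is another point the methodology leaves open: "cluster
mean against the global mean" can be read as cluster-vs-complement or
cluster-vs-fixed-constant. The default is the two-sample Welch test against
the complement, which is well defined at every cluster size and does not
treat the global mean as a known constant; `cluster_mean_test(mode =
"global_constant")` provides the one-sample reading. No multiple-testing
correction is applied by default (the significance threshold p < 0.01 is
set a priori); pass a smaller `alpha` for a Bonferroni-style correction.

## The synthetic benchmark

The national MCOD files are restricted, so `default_benchmark_spec()`
defines a fully synthetic stand-in: a 16-cluster latent-class model over a
49-category demo vocabulary. Given the cluster, every category is present
independently with the cluster's prevalence; if no category is drawn the
cluster's highest-prevalence category is forced (keeping expected record
counts exact rather than rejection-sampling), and the underlying cause is
drawn from the present categories with prevalence-proportional weights.
Ages are truncated normal on [0, 130]; demographics are cluster-specific
categorical draws; attribute missingness matches the share of records
missing each attribute in published mortality tabulations (education 3.3%,
marital status 1.0%, place of death 0.5%, manner of death 19.1%).

Cluster structure: twelve chronic-disease clusters each carry a disjoint
*triple* of signature conditions at prevalences 0.95 / 0.80 / 0.50 over a
background prevalence of 0.03; one acute cardiac cluster and three
external-cause clusters (poisoning, open wound/suffocation, other physical
harm) are near-single-condition, the external ones with young ages and
non-natural manners of death. Signature triples, rather than pairs, are
what make the planted structure recoverable at the record level: with
pairs, the ~15–20% of records missing one signature while carrying several
background conditions migrate to foreign map regions and cap the achievable
adjusted Rand index below 0.9. The mixture weights, prevalences and age
parameters were calibrated once, by simulation, so that at n = 100,000 the
generated margins land on the published gross margins — about 3.0
conditions per record, 78% multimorbidity, mean age 73 — and then frozen.

What the benchmark does *not* emulate: within-cluster dependence between
conditions beyond cluster membership (no comorbidity correlations inside a
cluster), code-level heterogeneity (one representative ICD-10 code per
category), temporal trends across registration years, and the long tail of
rare categories a 346-category vocabulary carries. A high ARI on this
benchmark therefore shows the pipeline recovers well-separated latent
structure at realistic margins; it does not show that real mortality data
contain sixteen clusters, nor that real clusters are this separable.

## Problem sizes and numerics

The package's reference configuration (`pipeline_config()` defaults) is a
desk-scale choice: n = 100,000 synthetic records, a 16×16 map (256 nodes)
trained for 20 epochs on a 20,000-record sample, then all records mapped
and clustered at k = 16. A population-scale run would use the conventional
~1,000-node map (`default_som_grid()`, aspect ratio from the first two
principal-axis standard deviations, clamped to [1, 4]) and a training
sample bounded at 200,000 — the algorithms are identical, only the sizes
grow. At the reference size the full pipeline, including generation and
profiling, completes in well under a minute on one CPU.

Numerical conventions: BMU and merge ties break to lowest indices;
merge-cost comparisons use a relative tolerance of 1e−12 when detecting
ties; malformed input rows (bad ICD-10 syntax, >20 condition codes, ages
outside [0, 130]) are skipped and counted rather than fatal; empty clusters
and all-missing attributes are flagged unavailable rather than producing
NaN statistics; and every stochastic stage (sampling, initialization,
synthesis) is driven by one user-supplied seed, making whole-pipeline runs
byte-reproducible.

## Known limitations

* The map geometry, training schedule and attribute scaling of the
  commercial SOM suite used in the original large-scale analysis are
  unpublished; results here are method-faithful, not bit-faithful, and no
  attempt is made to reproduce its proprietary cluster-significance
  heuristics or per-attribute "priority" scaling.
* The 49-category demo map is illustrative: its prefix rules cover the
  categories that drive the named clusters plus common comorbidities, not
  the complete ICD-10 code space (unmatched codes fall into `other`).
  Substantive analyses must supply their own aggregation table.
* `choose_k()` is a heuristic; with a contiguity-constrained dendrogram the
  cost sequence need not be monotone and the "largest relative jump" can be
  ambiguous on flat cost profiles (the tie rule then returns the smallest
  candidate).
* Record-axis condition coding (a second, differently normalized code list
  on US certificates) is out of scope; one entity-axis condition list per
  record is assumed.
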