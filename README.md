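# somward

Clustering multiple-cause-of-death (MCOD) records by the health conditions
recorded on the death certificate.

US death certificates list not only a single underlying cause of death but
up to 20 entity-axis ICD-10 condition codes — the health conditions present
at death. Aggregating those codes into disease categories and clustering the
resulting binary profiles reveals population-level multimorbidity patterns:
who dies with what combinations of conditions, at what age, where, and from
which underlying causes. Classical hierarchical clustering is infeasible at
the scale of national mortality files (tens of millions of records), so this
package implements the standard two-stage workaround used in big-health-data
exploration:

1. **Self-organizing map (SOM).** Records are encoded as binary indicator
   vectors over the disease-category vocabulary and summarized by a batch
   Kohonen map: per epoch every training row is assigned to its
   best-matching unit (BMU) `c(x) = argmin_i ||x - m_i||`, and each node is
   updated to the kernel-weighted mean
   `m_i = Σ_j h(d(c_j, i), σ_t) x_j / Σ_j h(d(c_j, i), σ_t)` with Gaussian
   neighborhood `h(d, σ) = exp(-d² / 2σ²)` over lattice distance and a
   linearly shrinking radius σ_t. The map is trained on a seeded random
   sample; the full data are then mapped through it.
2. **SOM-Ward clustering.** Map nodes (centroid = codebook vector, weight =
   mapped record count) are agglomerated with Ward's minimum-variance
   criterion, merge cost `Δ = (w_a w_b / (w_a + w_b)) ||μ_a - μ_b||²`,
   restricted to lattice-adjacent clusters, so every cluster is a connected
   map region. Records inherit the cluster of their BMU.
3. **Profiling.** Per cluster: attribute summaries (`n (%)` with non-missing
   denominators for demographics, `mean (SD)` for continuous attributes,
   full-`n` percentages for condition prevalences), two-sided Welch t-tests
   of each cluster against its complement (significance at p < 0.01), and
   top-5 condition / underlying-cause rankings.

The national mortality files themselves are restricted, so the package
includes a latent-class synthetic generator (`generate_population()`,
`default_benchmark_spec()`) that emulates their structure — 16 planted
condition clusters, demographic distributions, attribute missingness —
calibrated to the published gross margins (about 3.0 conditions per record,
78% multimorbidity, mean age at death 73). The full 346-category ICD-10
aggregation is an external configuration; a 49-category demo map
(`demo_category_map()`) ships with the package.

## Worked example

```r
library(somward)

cfg <- pipeline_config(
  population_spec = default_benchmark_spec(n_records = 20000L),
  sample_size = 10000L, seed = 7
)
res <- run_pipeline(cfg)
#> records: parsed 20000, malformed 0, omitted 0, usable 20000

res$som
#> <som_model> 16 x 16 grid, 49-dim codebook, 20 epochs (QE 1.514 -> 0.8121)
res$clusters
#> <som_ward> 16 clusters over 16 x 16 grid; weights: 2,927, 1,996, 1,830, 1,799, 1,779, ...
```

The population table reproduces the conventions of published mortality
tables — counts with thousands separators, percentages over non-missing
denominators, half-up rounding:

```r
format_population_table(res$profiles)
#>      section                                    characteristic         display
#>          age                              Age at death (years)   73.15 (20.35)
#>          sex                                            Female  8,671 (43.36%)
#>      marital                                           Married  7,215 (36.43%)
#>       manner                                          Accident  2,470 (15.27%)
#>   conditions Different Health Conditions associated with Death     3.00 (1.56)
#>  multimorbid                                       Multimorbid 15,818 (79.09%)
```

The largest cluster is a cardiovascular-disease cluster; its top-5 most
prevalent conditions are the share of cluster records carrying each
category:

```r
dplyr::filter(res$profiles$top_conditions, cluster == "1")
#>  cluster rank                      category count  pct
#>        1    1                 heart_failure  2770 94.6
#>        1    2 atherosclerotic_heart_disease  2366 80.8
#>        1    3           atrial_fibrillation  1426 48.7
#>        1    4                     poisoning   110  3.8
#>        1    5      gastrointestinal_disease   106  3.6
```

Because the benchmark population has known latent clusters, recovery can be
scored with the adjusted Rand index:

```r
mclust::adjustedRandIndex(res$labels, res$latent$cluster)
#> [1] 0.923
```

`autoplot(res$som)` shows the quantization-error trace,
`autoplot(res$clusters)` the cluster map, and
`plot_component_plane(component_plane(res$som, res$assignment,
res$coded$age_years))` the per-node mean age — the numeric equivalent of
the colored map displays used to read where on the map old age, a
demographic share, or a condition concentrates. Fitted objects have
broom-style `tidy()` and `glance()` methods.

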