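Package: somward
Title: Self-Organizing-Map Ward Clustering of Multiple-Cause-of-Death Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters multiple-cause-of-death (MCOD) mortality records by the
    health conditions recorded on the death certificate. ICD-10 entity-axis
    condition codes are aggregated into disease categories and encoded as a
    binary indicator matrix; a batch-trained self-organizing map (SOM) gives
    an ordered low-dimensional representation; map nodes are agglomerated
    with Ward's minimum-variance criterion restricted to lattice-adjacent
    clusters (SOM-Ward); and clusters are profiled with per-attribute
    summaries, Welch t-tests against the complement, and top-5
    condition/cause rankings. A latent-class synthetic record generator with
    planted cluster structure stands in for the restricted national vital
    statistics files so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
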