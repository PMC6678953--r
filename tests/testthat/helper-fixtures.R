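# shared fixtures and independent oracles

tiny_map <- function(fallback = "other_bucket") {
  category_map(
    tibble::tibble(
      prefix = c("I25", "I46", "C34", "C", "J44", "F03"),
      label = c("atherosclerotic_heart_disease", "cardiac_arrest",
                "lung_cancer", "other_cancer", "copd", "dementia")
    ),
    fallback = fallback
  )
}

# build a raw record tibble the way read_mcod() would return it
make_records <- function(conds, underlying = NULL, age = NULL, sex = NULL,
                         ...) {
  n <- length(conds)
  tibble::tibble(
    record_id = sprintf("t%03d", seq_len(n)),
    data_year = rep(2010L, n),
    age_years = age %||% rep(70L, n),
    sex = sex %||% rep("female", n),
    race = rep("white", n),
    education = rep("secondary", n),
    marital = rep("married", n),
    resident_status = rep("local", n),
    place_of_death = rep("home", n),
    manner = rep("natural", n),
    underlying_cause = underlying %||% vapply(conds, function(v) {
      if (length(v)) v[[1]] else NA_character_
    }, character(1)),
    entity_conditions = conds,
    ...
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force nearest codebook row (independent of assign_bmus)
brute_bmu <- function(codebook, x) {
  d <- apply(codebook, 1L, function(m) sum((x - m)^2))
  which(d == min(d))[1L]
}

# textbook Welch two-sample t statistic and two-sided p
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# total weighted within-cluster sum of squares for a labeling of points
weighted_sse <- function(x, w, labels) {
  sum(vapply(unique(labels), function(l) {
    idx <- labels == l
    mu <- colSums(x[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
    sum(w[idx] * rowSums(sweep(x[idx, , drop = FALSE], 2L, mu)^2))
  }, numeric(1)))
}

# minimal som_model wrapper around an explicit codebook, for node-level tests
fake_som_model <- function(grid, codebook) {
  structure(
    list(grid = grid, codebook = as.matrix(codebook),
         schedule = list(n_epochs = 0L), qe_trace = numeric(0),
         sample_idx = integer(0)),
    class = "som_model"
  )
}

fake_assignment <- function(node_counts) {
  structure(
    list(bmu = rep.int(seq_along(node_counts), node_counts),
         node_counts = as.integer(node_counts)),
    class = "som_assignment"
  )
}

# hand contingency-table adjusted Rand index (independent of mclust)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
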