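test_that("half-up rounding follows the table convention", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-0.005, 2), -0.01)
  expect_equal(round_half_up(49.755, 2), 49.76)
  expect_equal(as_pct(0.49761, 2), 49.76)
  expect_equal(as_pct(0.87110, 1), 87.1)
})

test_that("categorical percentages use the non-missing denominator", {
  res <- categorical_percents(c(married = 10359202, widowed = 9633551,
                                divorced = 3930144, never_married = 3320267))
  expect_equal(res$pct[res$level == "married"], 38.02)
  expect_equal(sum(res$pct), 100, tolerance = 0.05)
  # binary prevalence uses the full group size instead
  expect_equal(binary_percent(21579345, 27525663), 78.40)
})

test_that("continuous summaries report mean and sample SD", {
  rec <- make_records(rep(list("I251"), 4), age = c(60L, 70L, 80L, 90L))
  coded <- code_records(rec, tiny_map())
  s <- summarize_attribute(coded, "age_years", "continuous")
  expect_equal(s$mean, 75)
  expect_equal(s$sd, sd(c(60, 70, 80, 90)))  # 12.9099...
  expect_equal(s$n, 4L)
})

test_that("the Welch test matches its closed form and flags significance", {
  res <- cluster_mean_test(1:5, 2:6)
  oracle <- welch_oracle(1:5, 2:6)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_false(res$significant)

  same <- cluster_mean_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_true(is.na(cluster_mean_test(5, 1:10)$t))   # n = 1 unavailable
  one_sample <- cluster_mean_test(c(4, 5, 6), mode = "global_constant", mu = 5)
  expect_equal(one_sample$t, 0)
})

test_that("the one-sample mode tests against the fixed global mean", {
  x <- c(10, 12, 14, 16)
  res <- cluster_mean_test(x, mode = "global_constant", mu = 9)
  ref <- stats::t.test(x, mu = 9)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("top-k lists rank by prevalence with alphabetical ties", {
  conds <- c(rep(list(c("I251", "I469")), 5),
             rep(list("I251"), 3),
             rep(list(c("C349", "J440")), 2))
  coded <- code_records(make_records(conds), tiny_map())
  top <- top_k_conditions(coded, k = 2)
  expect_equal(top$category[1], "atherosclerotic_heart_disease")
  expect_equal(top$pct[1], 80)
  expect_equal(top$category[2], "cardiac_arrest")
  # tie between lung_cancer and copd resolves alphabetically
  top4 <- top_k_conditions(coded, k = 4)
  expect_equal(top4$category[3:4], c("copd", "lung_cancer"))
  # k larger than the number of distinct categories returns them all
  expect_equal(nrow(top_k_conditions(coded, k = 10)), 4L)
  top_uc <- top_k_conditions(coded, k = 1, which = "underlying")
  expect_equal(top_uc$category, "atherosclerotic_heart_disease")
})

test_that("profiles cover every cluster plus the whole sample", {
  set.seed(2)
  n <- 400
  conds <- c(rep(list(c("I251", "I469")), n / 2), rep(list("C349"), n / 2))
  age <- c(rep(85L, n / 2), rep(45L, n / 2)) + sample(-3:3, n, TRUE)
  rec <- make_records(conds, age = age)
  coded <- code_records(rec, tiny_map())
  labels <- rep(c(1L, 2L), each = n / 2)
  prof <- profile_clusters(coded, labels)
  expect_s3_class(prof, "cluster_profiles")
  expect_equal(sum(prof$sizes), n)

  ages <- dplyr::filter(prof$summaries, attribute == "age_years",
                        cluster != "all")
  expect_true(all(ages$significant))
  expect_true(prod(ages$t) < 0)          # opposite signs
  expect_true(all(ages$p < 0.01))

  # global rows are unaffected by the labeling
  prof2 <- profile_clusters(coded, rev(labels))
  g1 <- dplyr::filter(prof$summaries, cluster == "all")
  g2 <- dplyr::filter(prof2$summaries, cluster == "all")
  expect_equal(g1, g2)
})

test_that("categorical level counts sum to their denominator in every cluster", {
  pop <- generate_population(default_benchmark_spec(n_records = 3000L),
                             seed = 14)
  coded <- filter_usable(code_records(pop$records, demo_category_map()))
  labels <- as.integer(factor(pop$latent$cluster[
    pop$latent$record_id %in% coded$record_id]))
  prof <- profile_clusters(coded, labels,
                           attributes = c(sex = "categorical",
                                          manner = "categorical",
                                          education = "categorical",
                                          multimorbid = "binary"))
  sums <- dplyr::summarize(
    dplyr::group_by(
      dplyr::filter(prof$summaries, kind == "categorical", !is.na(count)),
      cluster, attribute
    ),
    total_pct = sum(pct), n = dplyr::first(n), total_count = sum(count)
  )
  expect_true(all(abs(sums$total_pct - 100) <= 0.05))
  expect_true(all(sums$total_count == sums$n))
})

test_that("a single-cluster labeling flags its tests unavailable", {
  coded <- code_records(make_records(rep(list("I251"), 6)), tiny_map())
  prof <- profile_clusters(coded, rep(1L, 6),
                           attributes = c(age_years = "continuous"))
  row <- dplyr::filter(prof$summaries, cluster != "all")
  expect_true(is.na(row$t))
})

test_that("misaligned labels are rejected", {
  coded <- code_records(make_records(rep(list("I251"), 4)), tiny_map())
  expect_error(profile_clusters(coded, 1:3), class = "somward_profile")
})

test_that("co-occurrence shares follow the prose convention", {
  conds <- c(rep(list(c("F039", "I251")), 7), rep(list("F039"), 3),
             rep(list("I251"), 5))
  coded <- code_records(make_records(conds), tiny_map())
  res <- co_occurrence_share(coded, "dementia")
  expect_equal(res$n_with, 10L)
  expect_equal(res$n_with_other, 7L)
  expect_equal(res$pct, 70.0)
  expect_error(co_occurrence_share(coded, "copd"), class = "somward_profile")
})

test_that("the population table is internally consistent", {
  pop <- generate_population(default_benchmark_spec(n_records = 2000L),
                             seed = 16)
  coded <- filter_usable(code_records(pop$records, demo_category_map()))
  prof <- profile_clusters(coded, rep(1L, nrow(coded)))
  tab <- format_population_table(prof)
  expect_true(all(c("Female", "Married", "Natural", "Multimorbid") %in%
                    tab$characteristic))
  mm <- tab$display[tab$characteristic == "Multimorbid"]
  count <- as.numeric(gsub("[,()%]| \\(.*", "", mm))
  pct <- as.numeric(sub(".*\\(([0-9.]+)%\\)", "\\1", mm))
  expect_equal(count, sum(coded$multimorbid))
  expect_equal(pct, binary_percent(sum(coded$multimorbid), nrow(coded)))
})
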