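test_that("pca_plane initialization degenerates to the column means on 1x1", {
  x <- matrix(runif(60), 20, 3)
  cb <- init_codebook(x, som_grid(1, 1))
  expect_equal(as.vector(cb), unname(colMeans(x)))
})

test_that("pca_plane on two antipodal points spans their axis symmetrically", {
  v <- c(2, -1, 0.5)
  x <- rbind(v, -v)
  cb <- init_codebook(x, som_grid(1, 2))
  # both codebook vectors on the line spanned by v, symmetric about 0
  expect_equal(cb[1, ], -cb[2, ], ignore_attr = TRUE)
  cross <- cb[1, ] / v
  expect_equal(max(cross) - min(cross), 0, tolerance = 1e-10)
})

test_that("zero-variance data fall back to a constant plane with a warning", {
  x <- matrix(1, 10, 3)
  expect_warning(cb <- init_codebook(x, som_grid(2, 2)), "zero-variance")
  expect_true(all(cb == 1))
})

test_that("random initialization is seeded and reproducible", {
  x <- matrix(runif(200), 50, 4)
  a <- init_codebook(x, som_grid(3, 3), method = "random", seed = 7)
  b <- init_codebook(x, som_grid(3, 3), method = "random", seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, init_codebook(x, som_grid(3, 3),
                                          method = "random", seed = 8)))
})

test_that("find_bmu matches exact codebook rows and breaks ties downward", {
  cb <- matrix(seq_len(24), 6, 4)
  expect_equal(find_bmu(cb, cb[5, ]), 5L)
  same <- matrix(1, 4, 3)
  expect_equal(find_bmu(same, c(9, 9, 9)), 1L)
  expect_error(find_bmu(cb, 1:3), class = "somward_dim")
})

test_that("find_bmu agrees with an exhaustive distance scan", {
  set.seed(31)
  cb <- matrix(runif(6 * 8), 6, 8)
  for (i in 1:20) {
    x <- runif(8)
    expect_equal(find_bmu(cb, x), brute_bmu(cb, x))
  }
})

test_that("a 1x1 grid collapses to the sample mean after one epoch", {
  x <- matrix(runif(90), 30, 3)
  m <- som_train(x, som_grid(1, 1), n_epochs = 1, sigma_start = 2,
                 sigma_end = 2)
  expect_equal(as.vector(m$codebook), unname(colMeans(x)), tolerance = 1e-12)
})

test_that("a zero-radius batch epoch is one k-means (Lloyd) update", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:40, 1)
    d <- sample(2:4, 1)
    k <- sample(2:5, 1)
    x <- matrix(runif(n * d), n, d)
    cb0 <- x[sample.int(n, k), , drop = FALSE]
    m <- som_train(x, som_grid(1, k), n_epochs = 1,
                   sigma_start = 1e-6, sigma_end = 1e-6, codebook = cb0)
    # brute-force Lloyd update from the same starting centroids
    assign0 <- apply(x, 1, function(r) brute_bmu(cb0, r))
    expected <- cb0
    for (j in unique(assign0)) {
      expected[j, ] <- colMeans(x[assign0 == j, , drop = FALSE])
    }
    expect_equal(m$codebook, expected, tolerance = 1e-9, ignore_attr = TRUE)
    # and the implied assignments agree
    expect_equal(assign_to <- map_records(m, x)$bmu,
                 apply(x, 1, function(r) brute_bmu(m$codebook, r)))
  }
})

test_that("training reduces quantization error under the default schedule", {
  pop <- generate_population(default_benchmark_spec(n_records = 4000L),
                             seed = 12)
  coded <- filter_usable(code_records(pop$records, demo_category_map()))
  x <- build_indicator_matrix(coded, demo_category_map()$vocabulary)
  m <- som_train(x, som_grid(8, 8), seed = 2)
  expect_lt(utils::tail(m$qe_trace, 1), m$qe_trace[1])
  # convex-combination updates keep binary codebooks inside [0, 1]
  expect_true(all(m$codebook >= 0 & m$codebook <= 1))
})

test_that("training is deterministic given the seed", {
  x <- matrix(runif(600), 200, 3)
  a <- som_train(x, som_grid(4, 4), n_epochs = 5, sample_size = 100, seed = 3)
  b <- som_train(x, som_grid(4, 4), n_epochs = 5, sample_size = 100, seed = 3)
  expect_identical(a$codebook, b$codebook)
  expect_identical(a$qe_trace, b$qe_trace)
})

test_that("mapping conserves records and self-maps codebook rows", {
  cb <- matrix(runif(20), 5, 4)
  m <- fake_som_model(som_grid(1, 5), cb)
  a <- map_records(m, cb)
  expect_equal(a$bmu, 1:5)
  expect_equal(a$node_counts, rep(1L, 5))
  empty <- map_records(m, cb[0, , drop = FALSE])
  expect_length(empty$bmu, 0L)
  expect_equal(sum(empty$node_counts), 0L)
  x <- matrix(runif(120), 30, 4)
  expect_equal(sum(map_records(m, x)$node_counts), 30L)
})

test_that("quantization error equals the mean record-to-BMU distance", {
  m <- fake_som_model(som_grid(1, 1), matrix(0, 1, 2))
  x <- rbind(c(3, 0), c(0, 5))
  expect_equal(quantization_error(m, x), 4)
  m2 <- fake_som_model(som_grid(1, 3), matrix(runif(6), 3, 2))
  expect_equal(quantization_error(m2, m2$codebook), 0)
  set.seed(5)
  x <- matrix(runif(40), 20, 2)
  bmu <- apply(x, 1, function(r) brute_bmu(m2$codebook, r))
  manual <- mean(sqrt(rowSums((x - m2$codebook[bmu, ])^2)))
  expect_equal(quantization_error(m2, x), manual)
})

test_that("component planes average per node and flag empty nodes", {
  m <- fake_som_model(som_grid(2, 2), matrix(0, 4, 2))
  a <- fake_assignment(c(2L, 0L, 0L, 0L))
  plane <- component_plane(m, a, c(70, 80))
  expect_equal(plane$value[1], 75)
  expect_true(all(plane$empty[2:4]))
  expect_true(all(is.na(plane$value[2:4])))
  # missing values leave the denominator
  plane2 <- component_plane(m, a, c(70, NA))
  expect_equal(plane2$value[1], 70)
  expect_equal(plane2$n[1], 1L)
  # binary attributes become node fractions
  a3 <- fake_assignment(c(3L, 1L, 0L, 0L))
  plane3 <- component_plane(m, a3, c(1, 0, 1, 1))
  expect_true(all(plane3$value[!plane3$empty] >= 0 &
                    plane3$value[!plane3$empty] <= 1))
  expect_error(component_plane(m, a3, 1:3), class = "somward_dim")
})

test_that("SOM models round-trip through their text serialization", {
  x <- matrix(runif(300), 100, 3)
  m <- som_train(x, som_grid(3, 4), n_epochs = 3, seed = 1)
  stem <- file.path(withr::local_tempdir(), "som")
  write_som_model(m, stem)
  m2 <- read_som_model(stem)
  expect_equal(m2$codebook, m$codebook, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(m2$grid$n_nodes, m$grid$n_nodes)
  expect_equal(m2$qe_trace, m$qe_trace, tolerance = 1e-12)
})
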