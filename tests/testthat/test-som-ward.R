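# flood fill over lattice edges restricted to one cluster's nodes
is_connected_region <- function(nodes, edges) {
  if (length(nodes) <= 1L) return(TRUE)
  reach <- nodes[1]
  repeat {
    grow <- unique(c(
      edges$b[edges$a %in% reach & edges$b %in% nodes],
      edges$a[edges$b %in% reach & edges$a %in% nodes]
    ))
    new <- union(reach, grow)
    if (length(new) == length(reach)) break
    reach <- new
  }
  length(reach) == length(nodes)
}

test_that("lattice adjacency has the closed-form edge count", {
  expect_equal(nrow(node_adjacency(som_grid(2, 2))), 4L)
  expect_equal(nrow(node_adjacency(som_grid(1, 3))), 2L)
  expect_equal(nrow(node_adjacency(som_grid(5, 7))), 58L)
  e <- node_adjacency(som_grid(4, 4))
  expect_true(all(e$a < e$b))             # irreflexive, stored once
  expect_equal(anyDuplicated(paste(e$a, e$b)), 0L)
  # 8-connectivity adds 2 * (rows-1) * (cols-1) diagonal edges
  expect_equal(nrow(node_adjacency(som_grid(4, 4), connectivity = 8)),
               24L + 2L * 9L)
})

test_that("ward_cost equals the direct SSE increase of the merge", {
  expect_equal(ward_cost(c(1, 1), 3, c(1, 1), 5), 0)
  expect_equal(ward_cost(0, 1, 2, 1), 2)
  expect_error(ward_cost(0, 0, 1, 1), class = "somward_ward")
  set.seed(77)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    x <- matrix(runif(n * 3), n, 3)
    w <- sample(1:5, n, replace = TRUE)
    split <- sample(2:(n - 1), 1)
    a <- seq_len(split); b <- setdiff(seq_len(n), a)
    mu <- function(i) colSums(x[i, , drop = FALSE] * w[i]) / sum(w[i])
    sse_before <- weighted_sse(x, w, c(rep(1, split), rep(2, n - split)))
    sse_after <- weighted_sse(x, w, rep(1, n))
    expect_equal(ward_cost(mu(a), sum(w[a]), mu(b), sum(w[b])),
                 sse_after - sse_before, tolerance = 1e-10)
  }
})

test_that("k equal to the number of non-empty nodes is the identity clustering", {
  cb <- matrix(runif(12), 6, 2)
  m <- fake_som_model(som_grid(2, 3), cb)
  a <- fake_assignment(c(3L, 1L, 2L, 2L, 1L, 4L))
  cl <- som_ward_cluster(m, a, k = 6)
  expect_equal(cl$k, 6L)
  expect_equal(nrow(cl$dendrogram), 0L)
  expect_length(unique(cl$node_labels), 6L)
  # labels ordered by descending weight
  expect_equal(unname(cl$cluster_weights), sort(a$node_counts, TRUE))
})

test_that("on a monotone 1-D line the constraint is non-binding", {
  vals <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  m <- fake_som_model(som_grid(1, 6), matrix(vals, 6, 1))
  a <- fake_assignment(rep(1L, 6))
  cl <- som_ward_cluster(m, a, k = 2)
  expect_equal(cl$node_labels[1:3], rep(cl$node_labels[1], 3))
  expect_equal(cl$node_labels[4:6], rep(cl$node_labels[4], 3))
  expect_false(cl$node_labels[1] == cl$node_labels[4])
  # identical to unconstrained Ward at k = 2 (higher k has exact cost ties
  # whose order hclust resolves by its own convention)
  hc <- stats::hclust(stats::dist(vals)^2, method = "ward.D")
  expect_equal(ari_oracle(cl$node_labels, stats::cutree(hc, 2)), 1)
})

test_that("constrained and unconstrained Ward agree on random monotone lines", {
  set.seed(123)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    vals <- sort(runif(n, 0, 10))
    m <- fake_som_model(som_grid(1, n), matrix(vals, n, 1))
    a <- fake_assignment(rep(1L, n))
    hc <- stats::hclust(stats::dist(vals)^2, method = "ward.D")
    for (k in 2:4) {
      expect_equal(
        ari_oracle(som_ward_cluster(m, a, k = k)$node_labels,
                   stats::cutree(hc, k)),
        1
      )
    }
  }
})

test_that("every cluster is a connected lattice region", {
  set.seed(9)
  grid <- som_grid(6, 6)
  cb <- matrix(runif(36 * 4), 36, 4)
  counts <- rpois(36, 3)
  counts[sample(36, 6)] <- 0L           # some empty nodes
  m <- fake_som_model(grid, cb)
  a <- fake_assignment(as.integer(counts))
  edges <- node_adjacency(grid)
  for (k in c(2, 4, 7)) {
    cl <- som_ward_cluster(m, a, k = k)
    expect_equal(cl$k, k)
    for (lab in seq_len(k)) {
      expect_true(is_connected_region(which(cl$node_labels == lab), edges))
    }
  }
})

test_that("accepted merge costs account exactly for the final SSE", {
  set.seed(41)
  grid <- som_grid(4, 5)
  cb <- matrix(runif(20 * 3), 20, 3)
  counts <- sample(1:6, 20, replace = TRUE)
  m <- fake_som_model(grid, cb)
  a <- fake_assignment(as.integer(counts))
  cl <- som_ward_cluster(m, a, k = 3)
  direct <- weighted_sse(cb, counts, cl$node_labels)
  expect_equal(sum(cl$dendrogram$ward_cost), direct, tolerance = 1e-9)
})

test_that("empty nodes attach with zero weight and k is range-checked", {
  grid <- som_grid(1, 4)
  cb <- matrix(c(0, 1, 2, 3), 4, 1)
  m <- fake_som_model(grid, cb)
  a <- fake_assignment(c(2L, 0L, 0L, 5L))
  cl <- som_ward_cluster(m, a, k = 2)
  expect_equal(sum(cl$cluster_weights), 7)
  expect_true(all(cl$node_labels > 0L))
  expect_error(som_ward_cluster(m, a, k = 3), class = "somward_ward")
  expect_error(som_ward_cluster(m, fake_assignment(rep(0L, 4)), k = 1),
               class = "somward_ward")
})

test_that("record labeling conserves the cluster weights", {
  cb <- matrix(runif(16), 8, 2)
  m <- fake_som_model(som_grid(2, 4), cb)
  a <- fake_assignment(c(5L, 3L, 2L, 4L, 1L, 2L, 3L, 1L))
  cl <- som_ward_cluster(m, a, k = 3)
  labels <- label_records(a, cl)
  expect_equal(unname(as.vector(table(labels)[as.character(1:3)])),
               unname(as.integer(cl$cluster_weights)))
  one <- fake_assignment(c(0L, 7L, 0L, 0L, 0L, 0L, 0L, 0L))
  cl1 <- som_ward_cluster(m, one, k = 1)
  expect_true(all(label_records(one, cl1) == 1L))
})

test_that("record order does not affect the node-level clustering", {
  set.seed(61)
  grid <- som_grid(3, 3)
  cb <- matrix(runif(27), 9, 3)
  m <- fake_som_model(grid, cb)
  bmu <- sample.int(9, 40, replace = TRUE)
  a1 <- structure(list(bmu = bmu, node_counts = tabulate(bmu, 9)),
                  class = "som_assignment")
  a2 <- structure(list(bmu = rev(bmu), node_counts = tabulate(bmu, 9)),
                  class = "som_assignment")
  expect_identical(som_ward_cluster(m, a1, k = 3)$node_labels,
                   som_ward_cluster(m, a2, k = 3)$node_labels)
})

test_that("choose_k finds the largest relative cost jump", {
  dendro <- tibble::tibble(step = 1:4, cluster_a = 1:4, cluster_b = 2:5,
                           ward_cost = c(1, 1, 1, 100),
                           resulting_weight = 1, resulting_n_nodes = 1)
  expect_equal(choose_k(dendro), 2L)
  uniform <- dplyr::mutate(dendro, ward_cost = 2)
  expect_equal(choose_k(uniform), 2L)      # tie -> smallest k in range
  expect_error(choose_k(dendro[1, ]), class = "somward_ward")
})

test_that("choose_k recovers a planted two-block map", {
  grid <- som_grid(2, 6)
  block <- function(v) matrix(rep(v, 6), 6, 2, byrow = TRUE)
  cb <- rbind(block(c(1, 0)), block(c(0, 1))) +
    matrix(rnorm(24, sd = 0.01), 12, 2)
  m <- fake_som_model(grid, cb)
  a <- fake_assignment(rep(3L, 12))
  full <- som_ward_cluster(m, a, k = 1)
  expect_equal(choose_k(full), 2L)
  cl2 <- som_ward_cluster(m, a, k = 2)
  expect_equal(length(unique(cl2$node_labels[1:6])), 1L)
  expect_equal(length(unique(cl2$node_labels[7:12])), 1L)
})
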