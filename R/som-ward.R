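#' Lattice adjacency of a SOM grid
#'
#' 4-connectivity links horizontal and vertical lattice neighbors (edge count
#' `n_rows * (n_cols - 1) + n_cols * (n_rows - 1)`); 8-connectivity adds the
#' diagonals. The edge list is symmetric-irreflexive, stored once with
#' `a < b`.
#'
#' @param grid A [som_grid()].
#' @param connectivity 4 (default) or 8.
#' @return Tibble of edges (`a`, `b`), node ids 1-based row-major.
#' @export
node_adjacency <- function(grid, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- grid$n_rows; nc <- grid$n_cols
  id <- function(r, c) (r - 1L) * nc + c
  edges <- list()
  add <- function(r1, c1, r2, c2) {
    keep <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    if (any(keep)) {
      edges[[length(edges) + 1L]] <<-
        cbind(id(r1[keep], c1[keep]), id(r2[keep], c2[keep]))
    }
  }
  r <- grid$coords[, "row"]; c <- grid$coords[, "col"]
  add(r, c, r, c + 1L)
  add(r, c, r + 1L, c)
  if (connectivity == 8) {
    add(r, c, r + 1L, c + 1L)
    add(r, c, r + 1L, c - 1L)
  }
  e <- do.call(rbind, edges)
  tibble::tibble(a = pmin(e[, 1L], e[, 2L]), b = pmax(e[, 1L], e[, 2L]))
}

#' Ward merge cost
#'
#' The increase in total within-cluster (weighted) sum of squares caused by
#' merging two clusters with centroids `mu_a`, `mu_b` and weights `w_a`,
#' `w_b`: `w_a w_b / (w_a + w_b) * ||mu_a - mu_b||^2`.
#'
#' @param mu_a,mu_b Centroid vectors.
#' @param w_a,w_b Positive cluster weights (mapped record counts).
#' @return Scalar merge cost.
#' @export
ward_cost <- function(mu_a, w_a, mu_b, w_b) {
  if (w_a <= 0 || w_b <= 0) abort_somward("weights must be positive", "ward")
  (w_a * w_b / (w_a + w_b)) * sum((mu_a - mu_b)^2)
}

# attach empty nodes to the owner of their nearest non-empty node,
# walking outward over lattice edges so attachments stay connected
attach_empty_nodes <- function(grid, edges, nonempty) {
  n <- grid$n_nodes
  owner <- rep(NA_integer_, n)
  owner[nonempty] <- which(nonempty)
  nbr <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  frontier <- which(nonempty)
  while (anyNA(owner) && length(frontier)) {
    nxt <- integer(0)
    # lowest-index claimed neighbor wins; process frontier in index order
    for (node in sort(frontier)) {
      for (m in nbr[[node]]) {
        if (is.na(owner[m])) {
          owner[m] <- owner[node]
          nxt <- c(nxt, m)
        }
      }
    }
    frontier <- nxt
  }
  if (anyNA(owner)) abort_somward("map has no mapped records", "ward")
  owner
}

#' SOM-Ward clustering of map nodes
#'
#' Hierarchical Ward agglomeration restricted to the SOM topology: every
#' non-empty node starts as a singleton cluster (centroid = codebook vector,
#' weight = mapped record count; empty nodes are pre-attached with zero
#' weight to their nearest non-empty lattice neighbor so regions stay
#' connected), and at each step the *lattice-adjacent* pair with minimal
#' Ward cost is merged, until `k` clusters remain. Two clusters are adjacent
#' when any of their member nodes are lattice neighbors. Ties on cost go to
#' the lexicographically smallest pair of lowest member-node indices. Final
#' labels are 1..k in order of decreasing cluster weight.
#'
#' @param model A [som_train()] model.
#' @param assignment A [map_records()] result for the data being clustered.
#' @param k Target number of clusters (1 <= k <= number of non-empty nodes).
#' @param connectivity Lattice connectivity, see [node_adjacency()].
#' @return A `som_ward` object: `node_labels` (per node, 1..k),
#'   `k`, `cluster_weights` (records per cluster, decreasing), `dendrogram`
#'   (tibble of merges: `step`, `cluster_a`, `cluster_b` as representative
#'   node ids, `ward_cost`, `resulting_weight`, `resulting_n_nodes`),
#'   `centroids`, and the `grid`.
#' @export
som_ward_cluster <- function(model, assignment, k, connectivity = 4) {
  grid <- model$grid
  counts <- assignment$node_counts
  nonempty <- counts > 0
  n_active <- sum(nonempty)
  if (n_active == 0L) abort_somward("map has no mapped records", "ward")
  if (k < 1L || k > n_active) {
    abort_somward(
      paste0("k must be in [1, ", n_active, "] (non-empty nodes), got ", k),
      "ward"
    )
  }
  edges <- node_adjacency(grid, connectivity)
  owner <- attach_empty_nodes(grid, edges, nonempty)

  # cluster state, indexed by founding (non-empty) node id
  active <- which(nonempty)
  centroid <- model$codebook
  weight <- as.numeric(counts)
  members <- split(seq_len(grid$n_nodes), owner) # includes attached empties
  rep_node <- stats::setNames(
    vapply(members, min, integer(1)), names(members)
  )

  # cluster-level adjacency from lattice edges through the owner map
  ea <- owner[edges$a]; eb <- owner[edges$b]
  keep <- ea != eb
  pair_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  adj <- new.env(parent = emptyenv())
  for (kk in unique(pair_key(ea[keep], eb[keep]))) assign(kk, TRUE, adj)

  dendro <- list()
  step <- 0L
  while (length(active) > k) {
    best <- NULL
    for (key in ls(adj)) {
      ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
      i <- ij[1]; j <- ij[2]
      cost <- ward_cost(centroid[i, ], weight[i], centroid[j, ], weight[j])
      r1 <- min(rep_node[[as.character(i)]], rep_node[[as.character(j)]])
      r2 <- max(rep_node[[as.character(i)]], rep_node[[as.character(j)]])
      cand <- c(cost, r1, r2, i, j)
      if (is.null(best) ||
          cost < best[1] - 1e-12 * max(cost, best[1], 1) ||
          (abs(cost - best[1]) <= 1e-12 * max(cost, best[1], 1) &&
           (r1 < best[2] || (r1 == best[2] && r2 < best[3])))) {
        best <- cand
      }
    }
    i <- as.integer(best[4]); j <- as.integer(best[5])
    w <- weight[i] + weight[j]
    centroid[i, ] <- (weight[i] * centroid[i, ] + weight[j] * centroid[j, ]) / w
    weight[i] <- w
    ci <- as.character(i); cj <- as.character(j)
    members[[ci]] <- c(members[[ci]], members[[cj]])
    members[[cj]] <- NULL
    rep_node[[ci]] <- min(rep_node[[ci]], rep_node[[cj]])
    step <- step + 1L
    dendro[[step]] <- tibble::tibble(
      step = step,
      cluster_a = min(i, j), cluster_b = max(i, j),
      ward_cost = best[1],
      resulting_weight = w,
      resulting_n_nodes = length(members[[ci]])
    )
    # adjacency: j's neighbors become i's
    for (m in active) {
      if (m == i || m == j) next
      kj <- pair_key(j, m)
      if (!is.null(adj[[kj]])) {
        rm(list = kj, envir = adj)
        assign(pair_key(i, m), TRUE, adj)
      }
    }
    if (!is.null(adj[[pair_key(i, j)]])) rm(list = pair_key(i, j), envir = adj)
    active <- setdiff(active, j)
  }

  ord <- active[order(-weight[active],
                      vapply(as.character(active), function(ci) rep_node[[ci]],
                             integer(1)))]
  node_labels <- integer(grid$n_nodes)
  for (lab in seq_along(ord)) {
    node_labels[members[[as.character(ord[lab])]]] <- lab
  }
  structure(
    list(
      node_labels = node_labels,
      k = length(ord),
      cluster_weights = stats::setNames(weight[ord], seq_along(ord)),
      dendrogram = if (step) dplyr::bind_rows(dendro) else
        tibble::tibble(step = integer(0), cluster_a = integer(0),
                       cluster_b = integer(0), ward_cost = numeric(0),
                       resulting_weight = numeric(0),
                       resulting_n_nodes = integer(0)),
      centroids = centroid[ord, , drop = FALSE],
      grid = grid,
      connectivity = connectivity
    ),
    class = "som_ward"
  )
}

#' @export
print.som_ward <- function(x, ...) {
  cat("<som_ward> ", x$k, " clusters over ", x$grid$n_rows, " x ",
      x$grid$n_cols, " grid; weights: ",
      paste(utils::head(fmt_count(x$cluster_weights), 5), collapse = ", "),
      if (x$k > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Suggest a cluster count from the merge history
#'
#' Scans candidate counts `k` (default 2..30) and suggests the `k` with the
#' largest relative jump between the cost of the merge that would reduce `k`
#' to `k - 1` clusters and the preceding merge. Ties go to the smallest `k`
#' in the range. This selection rule is a pragmatic convention of this
#' package, not a published part of the method; an explicit user-supplied
#' `k` always overrides it.
#'
#' @param clusters A `som_ward` object run down to (or below) the candidate
#'   range, or its `dendrogram` tibble.
#' @param k_range Candidate counts searched.
#' @return Suggested `k` (integer).
#' @export
choose_k <- function(clusters, k_range = 2:30) {
  dendro <- if (inherits(clusters, "som_ward")) clusters$dendrogram else clusters
  m <- nrow(dendro)
  if (m < 2L) abort_somward("need at least two merges to suggest k", "ward")
  final_k <- if (inherits(clusters, "som_ward")) clusters$k else 1L
  n0 <- m + final_k
  # merge number (n0 - k + 1) reduces k clusters to k - 1
  cost_for <- function(k) dendro$ward_cost[n0 - k + 1L]
  ks <- sort(intersect(k_range, seq(max(2L, final_k + 1L), n0 - 1L)))
  if (!length(ks)) abort_somward("k_range outside the merge history", "ward")
  jump <- vapply(ks, function(k) {
    num <- cost_for(k); den <- cost_for(k + 1L)
    if (den <= 0) { if (num > 0) Inf else 1 } else num / den
  }, numeric(1))
  ks[which.max(jump)]
}

#' Label records through their best-matching units
#'
#' @param assignment A [map_records()] result.
#' @param clusters A [som_ward_cluster()] result for the same map.
#' @return Integer vector of per-record cluster labels (1..k); its histogram
#'   equals `clusters$cluster_weights` when `assignment` is the one the
#'   clustering was built from.
#' @export
label_records <- function(assignment, clusters) {
  clusters$node_labels[assignment$bmu]
}
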