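#' Define a rectangular SOM lattice
#'
#' Nodes live on an `n_rows` x `n_cols` rectangular grid; node ids are
#' row-major and 1-based; distance between nodes is the Euclidean distance
#' between their integer (row, col) coordinates.
#'
#' @param n_rows,n_cols Positive grid dimensions.
#' @return A `som_grid` with a `coords` matrix (node id, row, col).
#' @export
som_grid <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  coords <- cbind(
    row = rep(seq_len(n_rows), each = n_cols),
    col = rep(seq_len(n_cols), times = n_rows)
  )
  structure(list(n_rows = n_rows, n_cols = n_cols, coords = coords,
                 n_nodes = n_rows * n_cols),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$n_rows, " x ", x$n_cols, " rectangular lattice (",
      x$n_nodes, " nodes)\n", sep = "")
  invisible(x)
}

# pairwise Euclidean grid distances (n_nodes x n_nodes)
grid_distances <- function(grid) {
  as.matrix(stats::dist(grid$coords))
}

#' Pick a grid shape from the data
#'
#' Grid aspect ratio follows the ratio of the data's first two principal-axis
#' standard deviations, clamped to `[1, 4]`; the node budget defaults to
#' 1,000, the conventional size for population-scale maps (pass a smaller
#' budget for desk-scale runs).
#'
#' @param x Numeric data matrix (records x features).
#' @param n_nodes Approximate number of nodes wanted.
#' @return A [som_grid()].
#' @export
default_som_grid <- function(x, n_nodes = 1000L) {
  sv <- La.svd(scale(x, scale = FALSE), nu = 0, nv = 0)$d
  aspect <- if (length(sv) >= 2 && sv[2] > 0) sv[1] / sv[2] else 1
  aspect <- min(max(aspect, 1), 4)
  n_cols <- max(1L, as.integer(round(sqrt(n_nodes * aspect))))
  n_rows <- max(1L, as.integer(round(n_nodes / n_cols)))
  som_grid(n_rows, n_cols)
}

#' Initialize a SOM codebook
#'
#' `pca_plane` lays the codebook out linearly on the plane of the data's
#' first two principal axes, centered on the data mean (the long grid axis
#' follows the first axis); `random` samples codebook vectors uniformly from
#' observed rows.
#'
#' @param x Data matrix (rows = records, binary indicators or numeric).
#' @param grid A [som_grid()].
#' @param method `"pca_plane"` (default) or `"random"`.
#' @param seed Seed for `random` initialization.
#' @return Codebook matrix, `n_nodes` x `ncol(x)`.
#' @export
init_codebook <- function(x, grid, method = c("pca_plane", "random"),
                          seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort_somward("cannot initialize from empty data", "som")
  if (method == "random") {
    return(with_local_seed(seed, {
      x[sample.int(nrow(x), grid$n_nodes, replace = TRUE), , drop = FALSE]
    }))
  }
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- La.svd(xc, nu = 0, nv = 2)
  sdev <- sv$d / sqrt(max(1, nrow(x) - 1))
  if (sdev[1] <= .Machine$double.eps) {
    warning("zero-variance data; pca_plane initialization collapses to the mean")
    return(matrix(center, nrow = grid$n_nodes, ncol = ncol(x), byrow = TRUE))
  }
  axis_pos <- function(idx, n) {
    if (n == 1L) rep(0, length(idx)) else 2 * (idx - 1) / (n - 1) - 1
  }
  # long grid axis spans the first principal axis
  if (grid$n_cols >= grid$n_rows) {
    a1 <- axis_pos(grid$coords[, "col"], grid$n_cols)
    a2 <- axis_pos(grid$coords[, "row"], grid$n_rows)
  } else {
    a1 <- axis_pos(grid$coords[, "row"], grid$n_rows)
    a2 <- axis_pos(grid$coords[, "col"], grid$n_cols)
  }
  v1 <- sv$vt[1, ]
  v2 <- if (length(sv$d) >= 2 && sdev[2] > .Machine$double.eps) sv$vt[2, ] else 0 * v1
  sd2 <- if (length(sv$d) >= 2) sdev[2] else 0
  cb <- matrix(center, nrow = grid$n_nodes, ncol = ncol(x), byrow = TRUE) +
    outer(a1 * sdev[1], v1) + outer(a2 * sd2, v2)
  dimnames(cb) <- list(NULL, colnames(x))
  cb
}

# BMU assignment for a matrix of rows, chunked to bound memory;
# ties broken toward the lowest node index
assign_bmus <- function(codebook, x, chunk = 20000L) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(codebook)) {
    abort_somward("dimension mismatch between data and codebook", "dim")
  }
  n <- nrow(x)
  out <- integer(n)
  cb_sq <- rowSums(codebook^2)
  start <- 1L
  while (start <= n) {
    end <- min(n, start + chunk - 1L)
    xb <- x[start:end, , drop = FALSE]
    d2 <- sweep(-2 * tcrossprod(xb, codebook), 2L, cb_sq, "+")
    out[start:end] <- max.col(-d2, ties.method = "first")
    start <- end + 1L
  }
  out
}

#' Best-matching unit of a single record
#'
#' The node whose codebook vector has minimal Euclidean distance to `x`;
#' ties go to the lowest node index.
#'
#' @param model A [som_train()] model (or bare codebook matrix).
#' @param x Numeric vector of codebook dimension.
#' @return Node index (1-based).
#' @export
find_bmu <- function(model, x) {
  codebook <- if (is.matrix(model)) model else model$codebook
  if (length(x) != ncol(codebook)) {
    abort_somward("dimension mismatch between record and codebook", "dim")
  }
  assign_bmus(codebook, matrix(x, nrow = 1L))
}

#' Train a batch self-organizing map
#'
#' Batch Kohonen training: per epoch, every sample row is assigned to its
#' best-matching unit, then each node is replaced by the kernel-weighted mean
#' of all rows, with Gaussian neighborhood kernel
#' `h(d, sigma) = exp(-d^2 / (2 sigma^2))` over grid distance `d` and the
#' radius `sigma` interpolated linearly from `sigma_start` to `sigma_end`.
#' Nodes receiving zero kernel mass keep their previous vector. Because each
#' update is a convex combination of sample rows, codebook entries stay
#' within the sample's column ranges (within `[0, 1]` for indicator data).
#'
#' Training runs on a seeded random sample of at most `sample_size` rows —
#' the standard workflow for population-scale data, where the map is fitted
#' on a sample and the full data are then mapped through it with
#' [map_records()].
#'
#' @param x Indicator (or numeric) matrix, records x features.
#' @param grid A [som_grid()].
#' @param n_epochs Number of batch epochs (default 30).
#' @param sigma_start,sigma_end Neighborhood radii in grid-distance units;
#'   defaults `max(n_rows, n_cols) / 2` down to 0.5.
#' @param sample_size Maximum number of training rows (default
#'   `min(200000, nrow(x))`).
#' @param seed Seed controlling sampling and random initialization.
#' @param init Initialization method, see [init_codebook()].
#' @param codebook Optional explicit starting codebook (overrides `init`).
#' @return A `som_model`: `grid`, `codebook`, `schedule`, `qe_trace`
#'   (quantization error of the initial codebook followed by one value per
#'   epoch), and `sample_idx` (training rows used).
#' @export
som_train <- function(x, grid,
                      n_epochs = 30L,
                      sigma_start = max(grid$n_rows, grid$n_cols) / 2,
                      sigma_end = 0.5,
                      sample_size = min(200000L, nrow(x)),
                      seed = 1L,
                      init = c("pca_plane", "random"),
                      codebook = NULL) {
  init <- match.arg(init)
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort_somward("empty training sample", "som")
  stopifnot(n_epochs >= 1L, sigma_start >= sigma_end, sigma_end > 0)
  if (sample_size < grid$n_nodes) {
    warning("training sample smaller than the number of nodes")
  }
  sample_idx <- if (nrow(x) > sample_size) {
    with_local_seed(seed, sample.int(nrow(x), sample_size))
  } else {
    seq_len(nrow(x))
  }
  xs <- x[sample_idx, , drop = FALSE]
  if (is.null(codebook)) {
    codebook <- init_codebook(xs, grid, method = init, seed = seed)
  }
  stopifnot(nrow(codebook) == grid$n_nodes, ncol(codebook) == ncol(xs))

  gd2 <- grid_distances(grid)^2
  sigmas <- if (n_epochs == 1L) sigma_end else {
    seq(sigma_start, sigma_end, length.out = n_epochs)
  }
  xs_sq <- rowSums(xs^2)
  qe_of <- function(bmu, cb) {
    d2 <- xs_sq - 2 * rowSums(xs * cb[bmu, , drop = FALSE]) +
      rowSums(cb[bmu, , drop = FALSE]^2)
    mean(sqrt(pmax(d2, 0)))
  }
  qe_trace <- numeric(n_epochs + 1L)
  for (t in seq_len(n_epochs)) {
    bmu <- assign_bmus(codebook, xs)
    if (t == 1L) qe_trace[1L] <- qe_of(bmu, codebook)
    h <- exp(-gd2 / (2 * sigmas[t]^2))
    sums <- matrix(0, grid$n_nodes, ncol(xs))
    hit <- sort(unique(bmu))
    sums[hit, ] <- rowsum(xs, bmu)
    counts <- tabulate(bmu, nbins = grid$n_nodes)
    num <- h %*% sums
    den <- as.vector(h %*% counts)
    upd <- den > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    qe_trace[t + 1L] <- qe_of(assign_bmus(codebook, xs), codebook)
  }
  structure(
    list(
      grid = grid,
      codebook = codebook,
      schedule = list(n_epochs = n_epochs, sigma_start = sigma_start,
                      sigma_end = sigma_end, sample_size = length(sample_idx),
                      seed = seed, init = init),
      qe_trace = qe_trace,
      sample_idx = sample_idx
    ),
    class = "som_model"
  )
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model> ", x$grid$n_rows, " x ", x$grid$n_cols, " grid, ",
      ncol(x$codebook), "-dim codebook, ", x$schedule$n_epochs,
      " epochs (QE ", signif(utils::head(x$qe_trace, 1), 4), " -> ",
      signif(utils::tail(x$qe_trace, 1), 4), ")\n", sep = "")
  invisible(x)
}

#' Map records to their best-matching units
#'
#' Applies [find_bmu()] to every row of the full data (not only the training
#' sample) and tallies per-node record counts.
#'
#' @param model A `som_model`.
#' @param x Matrix with `ncol` equal to the codebook dimension.
#' @return A `som_assignment`: `bmu` (per-record node index) and
#'   `node_counts` (length `n_nodes`, sums to `nrow(x)`).
#' @export
map_records <- function(model, x) {
  x <- as.matrix(x)
  bmu <- if (nrow(x)) assign_bmus(model$codebook, x) else integer(0)
  structure(
    list(bmu = bmu,
         node_counts = tabulate(bmu, nbins = model$grid$n_nodes)),
    class = "som_assignment"
  )
}

#' @export
print.som_assignment <- function(x, ...) {
  cat("<som_assignment> ", length(x$bmu), " records on ",
      sum(x$node_counts > 0), "/", length(x$node_counts),
      " non-empty nodes\n", sep = "")
  invisible(x)
}

#' Quantization error
#'
#' Mean Euclidean distance of records to their BMU codebook vectors; the
#' standard SOM fit diagnostic.
#'
#' @param model A `som_model`.
#' @param x Data matrix.
#' @param assignment Optional precomputed [map_records()] result.
#' @return Mean distance (0 for an empty matrix is an error).
#' @export
quantization_error <- function(model, x, assignment = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort_somward("no records", "som")
  bmu <- (assignment %||% map_records(model, x))$bmu
  cb <- model$codebook[bmu, , drop = FALSE]
  mean(sqrt(pmax(rowSums((x - cb)^2), 0)))
}

#' Per-node attribute averages (component plane)
#'
#' The per-node mean of an attribute over the records mapped to each node —
#' the numeric content of the map displays used to read off, e.g., where on
#' the map average age at death is high. Missing values are excluded from
#' numerator and denominator; nodes with no non-missing records are flagged
#' empty (`value` NA, `empty` TRUE). For a binary attribute the plane value
#' is the node fraction in `[0, 1]`.
#'
#' @param model A `som_model` (supplies the grid layout).
#' @param assignment A [map_records()] result aligned with `values`.
#' @param values Numeric (or logical) per-record attribute vector.
#' @return Tibble: `node`, `row`, `col`, `n` (non-missing records), `value`,
#'   `empty`.
#' @export
component_plane <- function(model, assignment, values) {
  if (length(values) != length(assignment$bmu)) {
    abort_somward("values not aligned with mapped records", "dim")
  }
  values <- as.numeric(values)
  ok <- !is.na(values)
  n_nodes <- model$grid$n_nodes
  n <- tabulate(assignment$bmu[ok], nbins = n_nodes)
  sums <- rep(0, n_nodes)
  if (any(ok)) {
    s <- rowsum(values[ok], assignment$bmu[ok])
    sums[as.integer(rownames(s))] <- s[, 1L]
  }
  tibble::tibble(
    node = seq_len(n_nodes),
    row = model$grid$coords[, "row"],
    col = model$grid$coords[, "col"],
    n = n,
    value = ifelse(n > 0, sums / pmax(n, 1L), NA_real_),
    empty = n == 0L
  )
}

#' Export / import a SOM model as plain text
#'
#' The grid, schedule and quantization-error trace go to a YAML header; the
#' codebook goes to CSV (`node`, one column per category).
#'
#' @param model A `som_model`.
#' @param stem Path stem; writes `<stem>.yaml` and `<stem>_codebook.csv`.
#' @return Paths invisibly; `read_som_model()` returns the model.
#' @export
write_som_model <- function(model, stem) {
  header <- list(
    n_rows = model$grid$n_rows, n_cols = model$grid$n_cols,
    schedule = model$schedule, qe_trace = model$qe_trace
  )
  paths <- c(header = paste0(stem, ".yaml"),
             codebook = paste0(stem, "_codebook.csv"))
  yaml::write_yaml(header, paths[["header"]], precision = 15)
  cb_mat <- model$codebook
  if (is.null(colnames(cb_mat))) {
    colnames(cb_mat) <- paste0("V", seq_len(ncol(cb_mat)))
  }
  cb <- tibble::as_tibble(cb_mat)
  readr::write_csv(dplyr::bind_cols(tibble::tibble(node = seq_len(nrow(cb))), cb),
                   paths[["codebook"]], progress = FALSE)
  invisible(paths)
}

#' @rdname write_som_model
#' @export
read_som_model <- function(stem) {
  header <- yaml::read_yaml(paste0(stem, ".yaml"))
  cb <- readr::read_csv(paste0(stem, "_codebook.csv"),
                        col_types = readr::cols(), progress = FALSE)
  cb <- as.matrix(cb[, setdiff(names(cb), "node"), drop = FALSE])
  sched <- header$schedule
  structure(
    list(grid = som_grid(header$n_rows, header$n_cols), codebook = cb,
         schedule = sched, qe_trace = unlist(header$qe_trace),
         sample_idx = NULL),
    class = "som_model"
  )
}
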