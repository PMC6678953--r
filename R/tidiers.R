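#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a SOM model into a long node-by-category tibble
#'
#' @param x A `som_model`.
#' @param ... Unused.
#' @return Tibble: `node`, `row`, `col`, `category`, `value` (codebook
#'   entry).
#' @method tidy som_model
#' @export
tidy.som_model <- function(x, ...) {
  cb <- x$codebook
  tibble::tibble(
    node = rep(seq_len(nrow(cb)), times = ncol(cb)),
    row = rep(x$grid$coords[, "row"], times = ncol(cb)),
    col = rep(x$grid$coords[, "col"], times = ncol(cb)),
    category = rep(colnames(cb) %||% paste0("V", seq_len(ncol(cb))),
                   each = nrow(cb)),
    value = as.vector(cb)
  )
}

#' One-row training summary of a SOM model
#'
#' @param x A `som_model`.
#' @param ... Unused.
#' @return Tibble with grid shape, schedule and initial/final quantization
#'   error.
#' @method glance som_model
#' @export
glance.som_model <- function(x, ...) {
  tibble::tibble(
    n_rows = x$grid$n_rows, n_cols = x$grid$n_cols,
    n_nodes = x$grid$n_nodes, dim = ncol(x$codebook),
    n_epochs = x$schedule$n_epochs,
    sample_size = x$schedule$sample_size,
    initial_qe = x$qe_trace[1L],
    final_qe = utils::tail(x$qe_trace, 1L)
  )
}

#' Tidy a SOM-Ward clustering into a per-node tibble
#'
#' @param x A `som_ward` object.
#' @param ... Unused.
#' @return Tibble: `node`, `row`, `col`, `cluster`.
#' @method tidy som_ward
#' @export
tidy.som_ward <- function(x, ...) {
  tidy_som_ward_nodes(x)[, c("node", "row", "col", "cluster")]
}

#' One-row summary of a SOM-Ward clustering
#'
#' @param x A `som_ward` object.
#' @param ... Unused.
#' @return Tibble: `k`, `n_merges`, `total_merge_cost`,
#'   `largest_cluster_weight`.
#' @method glance som_ward
#' @export
glance.som_ward <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_merges = nrow(x$dendrogram),
    total_merge_cost = sum(x$dendrogram$ward_cost),
    largest_cluster_weight = unname(x$cluster_weights[1L])
  )
}

#' Tidy cluster profiles
#'
#' @param x A `cluster_profiles` object.
#' @param ... Unused.
#' @return The long summary tibble (cluster x attribute x level).
#' @method tidy cluster_profiles
#' @export
tidy.cluster_profiles <- function(x, ...) x$summaries

#' One-row summary of cluster profiles
#'
#' @param x A `cluster_profiles` object.
#' @param ... Unused.
#' @return Tibble: `k`, `n_records`, `n_significant` (summary rows with
#'   p below the threshold), `alpha`.
#' @method glance cluster_profiles
#' @export
glance.cluster_profiles <- function(x, ...) {
  tibble::tibble(
    k = length(x$sizes),
    n_records = sum(x$sizes),
    n_significant = sum(x$summaries$significant, na.rm = TRUE),
    alpha = x$alpha
  )
}

# re-export the broom verbs so tidy()/glance() work without attaching broom
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the quantization-error trace of a SOM
#'
#' @param object A `som_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot som_model
#' @export
autoplot.som_model <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$qe_trace) - 1L,
                       qe = object$qe_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$qe)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "batch epoch (0 = initialization)",
                  y = "quantization error") +
    ggplot2::theme_minimal()
}

#' Plot the cluster map of a SOM-Ward clustering
#'
#' @param object A `som_ward` object.
#' @param ... Unused.
#' @return A ggplot tile map of the lattice colored by cluster.
#' @method autoplot som_ward
#' @export
autoplot.som_ward <- function(object, ...) {
  df <- tidy.som_ward(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_tile(color = "grey30", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "cluster", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a component plane
#'
#' Tile map of a per-node attribute average, the numeric equivalent of the
#' colored map displays used to read where on the map age, a demographic
#' share, or a condition prevalence is high.
#'
#' @param plane Result of [component_plane()].
#' @param title Optional plot title.
#' @return A ggplot.
#' @export
plot_component_plane <- function(plane, title = NULL) {
  ggplot2::ggplot(plane, ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$value)) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_gradient(low = "#2c7bb6", high = "#d7191c",
                                 na.value = "grey95") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "mean") +
    ggplot2::theme_minimal()
}
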