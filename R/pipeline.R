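#' Assemble a pipeline configuration
#'
#' One configuration object drives the full run: data source (a synthetic
#' population spec or an MCOD-like file), category map, map geometry and
#' training schedule, cluster count, attributes to profile, and the seed
#' that propagates to every stochastic stage. May be read from YAML with
#' [read_pipeline_config()].
#'
#' @param source `"synthetic"` or `"mcod_file"`.
#' @param population_spec [population_spec()] for synthetic input (default:
#'   [default_benchmark_spec()]).
#' @param path,schema Input file and column schema for `mcod_file` input.
#' @param map A [category_map()] or path to one (default demo map).
#' @param n_rows,n_cols Grid dimensions (default 16 x 16, a desk-scale map;
#'   see [default_som_grid()] for a data-driven choice).
#' @param n_epochs,sigma_start,sigma_end,sample_size Training schedule,
#'   see [som_train()].
#' @param k Number of clusters (default 16).
#' @param attributes Attributes to profile, see
#'   [default_profile_attributes()].
#' @param alpha Significance threshold (default 0.01).
#' @param seed Seed for sampling, initialization and synthesis.
#' @param out_dir Optional artifact directory; when set, [run_pipeline()]
#'   writes all stage exports there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(source = c("synthetic", "mcod_file"),
                            population_spec = NULL,
                            path = NULL, schema = mcod_schema(),
                            map = NULL,
                            n_rows = 16L, n_cols = 16L,
                            n_epochs = 20L,
                            sigma_start = max(n_rows, n_cols) / 2,
                            sigma_end = 0.5,
                            sample_size = 20000L,
                            k = 16L,
                            attributes = default_profile_attributes(),
                            alpha = 0.01,
                            seed = 1L,
                            out_dir = NULL) {
  source <- match.arg(source)
  if (source == "mcod_file" && is.null(path)) {
    abort_somward("mcod_file input needs a path", "config")
  }
  structure(
    list(source = source, population_spec = population_spec, path = path,
         schema = schema, map = map, n_rows = n_rows, n_cols = n_cols,
         n_epochs = n_epochs, sigma_start = sigma_start,
         sigma_end = sigma_end, sample_size = sample_size, k = k,
         attributes = attributes, alpha = alpha, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config_path YAML file with any subset of the `pipeline_config`
#'   fields (paths for `map` and `population_spec`).
#' @export
read_pipeline_config <- function(config_path) {
  y <- yaml::read_yaml(config_path)
  if (!is.null(y$population_spec) && is.character(y$population_spec)) {
    y$population_spec <- read_population_spec(y$population_spec)
  }
  if (!is.null(y$schema)) y$schema <- utils::modifyList(mcod_schema(), y$schema)
  if (!is.null(y$attributes)) y$attributes <- unlist(y$attributes)
  do.call(pipeline_config, y)
}

#' Run the full clustering pipeline
#'
#' Executes, in order: data synthesis or ingest; category coding and the
#' usability filter; the indicator matrix; batch SOM training on a seeded
#' sample and mapping of all records; SOM-Ward clustering to `k` clusters;
#' record labeling; and cluster profiling. Identical config + seed give
#' identical results. Any stage failure aborts with the stage name in the
#' error.
#'
#' @param config A [pipeline_config()] (or path to a YAML one).
#' @return Invisibly, a list with `coded`, `matrix`, `som`, `assignment`,
#'   `clusters`, `labels`, `latent` (synthetic runs only), `profiles`, and
#'   `manifest` (seed, per-stage record counts, parameters). When
#'   `config$out_dir` is set, all stage artifacts are also written there as
#'   CSV/YAML/text.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_somward(paste0("pipeline stage '", name, "' failed: ",
                           conditionMessage(e)), "pipeline")
    })
  }
  map <- config$map
  if (is.null(map)) map <- demo_category_map()
  if (is.character(map)) map <- read_category_map(map)

  latent <- NULL
  records <- stage("input", {
    if (config$source == "synthetic") {
      spec <- config$population_spec %||% default_benchmark_spec()
      pop <- generate_population(spec, seed = config$seed)
      latent <- pop$latent
      pop$records
    } else {
      read_mcod(config$path, config$schema)
    }
  })
  n_parsed <- attr(records, "n_parsed") %||% nrow(records)
  n_malformed <- attr(records, "n_malformed") %||% 0L

  coded <- stage("code", code_records(records, map))
  usable <- stage("filter", filter_usable(coded))
  omitted <- attr(usable, "omitted_count")
  if (!is.null(latent)) latent <- latent[latent$record_id %in% usable$record_id, ]
  message("records: parsed ", n_parsed, ", malformed ", n_malformed,
          ", omitted ", omitted, ", usable ", nrow(usable))

  x <- stage("indicator_matrix", build_indicator_matrix(usable, map$vocabulary))
  grid <- som_grid(config$n_rows, config$n_cols)
  som <- stage("som_train", som_train(
    x, grid, n_epochs = config$n_epochs,
    sigma_start = config$sigma_start, sigma_end = config$sigma_end,
    sample_size = min(config$sample_size, nrow(x)), seed = config$seed
  ))
  assignment <- stage("map_records", map_records(som, x))
  clusters <- stage("som_ward", som_ward_cluster(som, assignment, config$k))
  labels <- stage("label_records", label_records(assignment, clusters))
  profiles <- stage("profiling", profile_clusters(
    usable, labels, attributes = config$attributes, alpha = config$alpha
  ))

  manifest <- list(
    package = as.character(utils::packageVersion("somward")),
    seed = config$seed,
    counts = list(parsed = n_parsed, malformed = n_malformed,
                  omitted = omitted, usable = nrow(usable)),
    grid = c(n_rows = grid$n_rows, n_cols = grid$n_cols),
    schedule = som$schedule[c("n_epochs", "sigma_start", "sigma_end",
                              "sample_size")],
    k = clusters$k,
    alpha = config$alpha,
    final_qe = utils::tail(som$qe_trace, 1),
    cluster_weights = as.list(stats::setNames(
      as.integer(clusters$cluster_weights),
      paste0("cluster_", seq_along(clusters$cluster_weights))
    ))
  )
  result <- list(coded = usable, matrix = x, som = som,
                 assignment = assignment, clusters = clusters,
                 labels = labels, latent = latent, profiles = profiles,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config)
  invisible(result)
}

write_pipeline_artifacts <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_coded_records(result$coded, file.path(dir, "coded_records.csv"))
  write_som_model(result$som, file.path(dir, "som_model"))
  readr::write_csv(tidy_som_ward_nodes(result$clusters,
                                       result$assignment$node_counts),
                   file.path(dir, "node_clusters.csv"), progress = FALSE)
  readr::write_csv(result$clusters$dendrogram,
                   file.path(dir, "dendrogram.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(record_id = result$coded$record_id, cluster = result$labels),
    file.path(dir, "record_labels.csv"), progress = FALSE
  )
  write_profiles(result$profiles, dir)
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

tidy_som_ward_nodes <- function(clusters, node_counts = NULL) {
  tibble::tibble(
    node = seq_len(clusters$grid$n_nodes),
    row = clusters$grid$coords[, "row"],
    col = clusters$grid$coords[, "col"],
    cluster = clusters$node_labels,
    node_count = node_counts %||% NA_integer_
  )
}
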