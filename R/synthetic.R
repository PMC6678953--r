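#' Specify one latent cluster of a synthetic population
#'
#' The generator uses a latent-class model: each record belongs to one
#' cluster; given the cluster, every disease category is present
#' independently with the cluster's prevalence. Demographics are drawn from
#' cluster-specific categorical distributions and ages from a truncated
#' normal on `[0, 130]`.
#'
#' @param label Cluster name.
#' @param weight Mixture weight (normalized across clusters).
#' @param condition_prevalence Named numeric vector over the category
#'   vocabulary, entries in `[0, 1]`, at least one positive.
#' @param age_mean,age_sd Age distribution in years before truncation.
#' @param sex_probs,race_probs,education_probs,marital_probs,resident_probs,place_probs,manner_probs
#'   Named probability vectors over the canonical attribute levels.
#' @param underlying_weights Named non-negative weights used to draw the
#'   underlying cause among the record's present categories; defaults to the
#'   condition prevalences (common conditions are more often underlying).
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(label, weight, condition_prevalence,
                         age_mean, age_sd,
                         sex_probs, race_probs, education_probs,
                         marital_probs, resident_probs, place_probs,
                         manner_probs,
                         underlying_weights = condition_prevalence) {
  spec <- list(
    label = label, weight = weight,
    condition_prevalence = condition_prevalence,
    age_mean = age_mean, age_sd = age_sd,
    sex_probs = sex_probs, race_probs = race_probs,
    education_probs = education_probs, marital_probs = marital_probs,
    resident_probs = resident_probs, place_probs = place_probs,
    manner_probs = manner_probs,
    underlying_weights = underlying_weights
  )
  class(spec) <- "cluster_spec"
  spec
}

#' Specify a synthetic MCOD population
#'
#' @param n_records Number of records to generate (>= 1).
#' @param clusters List of [cluster_spec()]s; weights are normalized.
#' @param missingness Named list of per-attribute missing probabilities in
#'   `[0, 1)`; defaults to rates matching large US mortality tabulations
#'   (education 3.3%, marital 1.0%, place of death 0.5%, manner 19.1%).
#' @param representative_codes Named vector category -> ICD-10 code used when
#'   emitting entity-axis codes; defaults to [demo_representative_codes()].
#' @param allow_empty_fraction Fraction of records stripped of all
#'   conditions, to exercise the usability filter (default 0: every record
#'   has at least one condition by construction).
#' @param seed Default RNG seed for [generate_population()].
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_records, clusters,
                            missingness = default_missingness(),
                            representative_codes = demo_representative_codes(),
                            allow_empty_fraction = 0,
                            seed = 1L) {
  spec <- list(
    n_records = as.integer(n_records), clusters = clusters,
    missingness = utils::modifyList(default_missingness(),
                                    as.list(missingness)),
    representative_codes = representative_codes,
    allow_empty_fraction = allow_empty_fraction,
    seed = as.integer(seed)
  )
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

#' Default per-attribute missingness of the synthetic generator
#'
#' Rates chosen to match the share of records missing each attribute in
#' published US multiple-cause mortality tables (manner of death is by far
#' the most incomplete field).
#' @return Named list of probabilities.
#' @export
default_missingness <- function() {
  list(age_years = 0, sex = 0, race = 0,
       education = 0.0331, marital = 0.0103, resident_status = 0,
       place_of_death = 0.0050, manner = 0.1908)
}

validate_population_spec <- function(spec) {
  problems <- character(0)
  need <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  need(spec$n_records >= 1L, "n_records must be >= 1")
  need(length(spec$clusters) >= 1L, "at least one cluster required")
  need(all(unlist(spec$missingness) >= 0 & unlist(spec$missingness) < 1),
       "missingness probabilities must be in [0, 1)")
  need(spec$allow_empty_fraction >= 0 && spec$allow_empty_fraction < 1,
       "allow_empty_fraction must be in [0, 1)")
  vocab <- names(spec$clusters[[1]]$condition_prevalence)
  for (cl in spec$clusters) {
    need(inherits(cl, "cluster_spec"), "clusters must be cluster_spec objects")
    need(identical(names(cl$condition_prevalence), vocab),
         paste0(cl$label, ": prevalence vocabulary differs between clusters"))
    need(all(cl$condition_prevalence >= 0 & cl$condition_prevalence <= 1),
         paste0(cl$label, ": prevalences must be in [0, 1]"))
    need(any(cl$condition_prevalence > 0),
         paste0(cl$label, ": needs at least one positive prevalence"))
    need(cl$weight > 0, paste0(cl$label, ": weight must be positive"))
    for (field in c("sex_probs", "race_probs", "education_probs",
                    "marital_probs", "resident_probs", "place_probs",
                    "manner_probs")) {
      need(abs(sum(cl[[field]]) - 1) < 1e-3,
           paste0(cl$label, ": ", field, " must sum to 1"))
    }
  }
  missing_codes <- setdiff(vocab, names(spec$representative_codes))
  need(length(missing_codes) == 0,
       paste0("no representative code for: ",
              paste(missing_codes, collapse = ", ")))
  if (length(problems)) {
    abort_somward(paste0("invalid population spec:\n- ",
                         paste(problems, collapse = "\n- ")), "spec")
  }
  invisible(spec)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# categorical draw per record: probs k x L, z cluster index, u uniforms
draw_categorical <- function(probs, z, u, levels) {
  cm <- t(apply(probs, 1L, cumsum))
  idx <- rowSums(u > cm[z, , drop = FALSE]) + 1L
  levels[pmin(idx, length(levels))]
}

#' Generate a synthetic MCOD population
#'
#' Draws, per record: a latent cluster by weight; each disease category
#' independently by the cluster's prevalence (if none is drawn the cluster's
#' highest-prevalence category is forced, so every record is usable); the
#' underlying cause from the present categories weighted by
#' `underlying_weights`; demographics from the cluster's distributions; and
#' missingness per attribute. The same spec and seed reproduce the output
#' exactly.
#'
#' @param spec A [population_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return List with `records` (tibble in the shape returned by
#'   [read_mcod()]) and `latent` (tibble of `record_id`, `cluster`).
#' @export
generate_population <- function(spec, seed = spec$seed) {
  validate_population_spec(spec)
  with_local_seed(seed, {
    n <- spec$n_records
    K <- length(spec$clusters)
    weights <- vapply(spec$clusters, `[[`, numeric(1), "weight")
    weights <- weights / sum(weights)
    vocab <- names(spec$clusters[[1]]$condition_prevalence)
    V <- length(vocab)
    P <- do.call(rbind, lapply(spec$clusters, `[[`, "condition_prevalence"))
    UW <- do.call(rbind, lapply(spec$clusters, `[[`, "underlying_weights"))
    labels <- vapply(spec$clusters, `[[`, character(1), "label")

    z <- sample.int(K, n, replace = TRUE, prob = weights)
    x <- matrix(stats::runif(n * V), n, V) < P[z, , drop = FALSE]
    empty <- rowSums(x) == 0L
    if (any(empty)) {
      top <- apply(P, 1L, which.max)
      x[cbind(which(empty), top[z[empty]])] <- TRUE
    }
    if (spec$allow_empty_fraction > 0) {
      n_empty <- round(spec$allow_empty_fraction * n)
      x[sample.int(n, n_empty), ] <- FALSE
    }

    # underlying cause via Gumbel-max over present categories
    w <- x * UW[z, , drop = FALSE]
    gumbel <- -log(-log(stats::runif(n * V)))
    score <- log(w) + gumbel
    score[w == 0] <- -Inf
    present <- rowSums(x) > 0L
    underlying_cat <- rep(NA_character_, n)
    underlying_cat[present] <- vocab[max.col(score[present, , drop = FALSE],
                                             ties.method = "first")]

    mu <- vapply(spec$clusters, `[[`, numeric(1), "age_mean")[z]
    sg <- vapply(spec$clusters, `[[`, numeric(1), "age_sd")[z]
    lo <- stats::pnorm(0, mu, sg)
    hi <- stats::pnorm(130, mu, sg)
    age <- as.integer(round(stats::qnorm(lo + stats::runif(n) * (hi - lo),
                                         mu, sg)))
    age <- pmin(pmax(age, 0L), 130L)

    draw_attr <- function(field, levels) {
      probs <- do.call(rbind, lapply(spec$clusters, function(cl) {
        p <- cl[[field]][levels]
        p[is.na(p)] <- 0
        p / sum(p)
      }))
      draw_categorical(probs, z, stats::runif(n), levels)
    }
    sex <- draw_attr("sex_probs", MCOD_LEVELS$sex)
    race <- draw_attr("race_probs", MCOD_LEVELS$race)
    education <- draw_attr("education_probs", MCOD_LEVELS$education)
    marital <- draw_attr("marital_probs", MCOD_LEVELS$marital)
    resident <- draw_attr("resident_probs", MCOD_LEVELS$resident_status)
    place <- draw_attr("place_probs", MCOD_LEVELS$place_of_death)
    manner <- draw_attr("manner_probs", MCOD_LEVELS$manner)
    year <- sample(2006:2016, n, replace = TRUE)

    miss <- function(vals, attr) {
      p <- spec$missingness[[attr]] %||% 0
      if (p > 0) vals[stats::runif(length(vals)) < p] <- NA
      vals
    }
    codes <- spec$representative_codes[vocab]
    conds <- lapply(seq_len(n), function(i) unname(codes[x[i, ]]))
    underlying_code <- ifelse(is.na(underlying_cat), NA_character_,
                              unname(codes[underlying_cat]))

    records <- tibble::tibble(
      record_id = sprintf("r%07d", seq_len(n)),
      data_year = year,
      age_years = miss(age, "age_years"),
      sex = miss(sex, "sex"),
      race = miss(race, "race"),
      education = miss(education, "education"),
      marital = miss(marital, "marital"),
      resident_status = miss(resident, "resident_status"),
      place_of_death = miss(place, "place_of_death"),
      manner = miss(manner, "manner"),
      underlying_cause = underlying_code,
      entity_conditions = conds
    )
    list(
      records = records,
      latent = tibble::tibble(record_id = records$record_id,
                              cluster = labels[z])
    )
  })
}

#' Write a generated population to disk
#'
#' Records go to `<stem>_records.csv` in the same delimited schema
#' [read_mcod()] reads (entity codes space-separated in one field); latent
#' cluster labels go to the sidecar `<stem>_latent.csv`.
#'
#' @param pop Result of [generate_population()].
#' @param stem Output path stem.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_population <- function(pop, stem) {
  rec <- dplyr::mutate(
    pop$records,
    entity_conditions = vapply(.data$entity_conditions, paste, "",
                               collapse = " ")
  )
  paths <- c(records = paste0(stem, "_records.csv"),
             latent = paste0(stem, "_latent.csv"))
  readr::write_csv(rec, paths[["records"]], progress = FALSE, na = "")
  readr::write_csv(pop$latent, paths[["latent"]], progress = FALSE)
  invisible(paths)
}

#' Read or write a population spec as YAML
#'
#' @param spec A [population_spec()].
#' @param path YAML file path.
#' @return `write_population_spec()` returns `path` invisibly;
#'   `read_population_spec()` returns a `population_spec`.
#' @export
write_population_spec <- function(spec, path) {
  ser <- list(
    n_records = spec$n_records,
    missingness = spec$missingness,
    representative_codes = as.list(spec$representative_codes),
    allow_empty_fraction = spec$allow_empty_fraction,
    seed = spec$seed,
    clusters = lapply(spec$clusters, function(cl) {
      lapply(unclass(cl), function(f) if (is.numeric(f)) as.list(f) else f)
    })
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  y <- yaml::read_yaml(path)
  clusters <- lapply(y$clusters, function(cl) {
    num <- function(f) unlist(cl[[f]])
    cluster_spec(
      label = cl$label, weight = cl$weight,
      condition_prevalence = num("condition_prevalence"),
      age_mean = cl$age_mean, age_sd = cl$age_sd,
      sex_probs = num("sex_probs"), race_probs = num("race_probs"),
      education_probs = num("education_probs"),
      marital_probs = num("marital_probs"),
      resident_probs = num("resident_probs"),
      place_probs = num("place_probs"), manner_probs = num("manner_probs"),
      underlying_weights = num("underlying_weights")
    )
  })
  population_spec(
    n_records = y$n_records, clusters = clusters,
    missingness = y$missingness,
    representative_codes = unlist(y$representative_codes),
    allow_empty_fraction = y$allow_empty_fraction %||% 0,
    seed = y$seed %||% 1L
  )
}
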