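#' Percentage breakdown of a categorical count table
#'
#' Implements the reporting convention of large mortality tables: the
#' denominator for a categorical attribute is the *non-missing* count, i.e.
#' the sum of the printed level counts, not the full record count.
#' Percentages are rounded half-up.
#'
#' @param counts Named numeric vector of per-level counts.
#' @param digits Decimal places (2 for tables, 1 for prose-style exports).
#' @return Tibble: `level`, `count`, `pct` (percent of the non-missing
#'   denominator).
#' @examples
#' categorical_percents(c(married = 10359202, widowed = 9633551,
#'                        divorced = 3930144, never_married = 3320267))
#' @export
categorical_percents <- function(counts, digits = 2) {
  denom <- sum(counts)
  tibble::tibble(
    level = names(counts),
    count = unname(as.numeric(counts)),
    pct = unname(as_pct(counts / denom, digits))
  )
}

#' Percentage of a binary indicator over the full group size
#'
#' Condition-prevalence style reporting: the denominator is the full group
#' `n` (every usable record has a defined condition set), unlike
#' [categorical_percents()].
#'
#' @param count Number of records with the indicator set.
#' @param n Full group size.
#' @param digits Decimal places.
#' @return Percent, rounded half-up.
#' @export
binary_percent <- function(count, n, digits = 2) {
  as_pct(count / n, digits)
}

#' Welch test of a cluster mean against its complement
#'
#' The default reading of "cluster mean tested against the global mean":
#' a two-sided two-sample Welch t-test of the cluster's values against the
#' values of all other records, which is well defined at any cluster size
#' short of the whole sample. The alternative `global_constant` mode runs a
#' one-sample t-test of the cluster against the fixed global mean `mu`.
#' Significance uses the study's a-priori threshold p < 0.01 by default (no
#' multiple-testing correction; pass `alpha = 0.01 / n_tests` for a
#' Bonferroni-style adjustment).
#'
#' @param cluster_values Numeric values in the cluster (NAs dropped).
#' @param complement_values Values outside the cluster (`welch` mode).
#' @param mode `"welch"` (default) or `"global_constant"`.
#' @param mu Global mean for `global_constant` mode.
#' @param alpha Significance threshold on the two-sided p-value.
#' @return Tibble: `t`, `df`, `p`, `significant`. All NA when either side
#'   has fewer than 2 non-missing values or no variance is available.
#' @export
cluster_mean_test <- function(cluster_values, complement_values = NULL,
                              mode = c("welch", "global_constant"),
                              mu = NULL, alpha = 0.01) {
  mode <- match.arg(mode)
  x <- cluster_values[!is.na(cluster_values)]
  unavailable <- tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                                significant = NA)
  res <- tryCatch({
    if (mode == "welch") {
      y <- complement_values[!is.na(complement_values)]
      if (length(x) < 2L || length(y) < 2L) return(unavailable)
      stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
    } else {
      if (length(x) < 2L || is.null(mu)) return(unavailable)
      stats::t.test(x, mu = mu, alternative = "two.sided")
    }
  }, error = function(e) NULL)
  if (is.null(res)) return(unavailable)
  tibble::tibble(
    t = unname(res$statistic),
    df = unname(res$parameter),
    p = res$p.value,
    significant = res$p.value < alpha
  )
}

#' Summarize one attribute for a cluster (or the whole sample)
#'
#' Continuous attributes get mean, sample SD and the non-missing `n`;
#' categorical attributes get per-level counts and percentages over the
#' non-missing denominator; binary attributes (condition indicators,
#' multimorbidity) get count and percentage over the full cluster `n`. When
#' `cluster_mask` is given, each summary row also carries the Welch test of
#' the cluster against its complement (for categorical attributes, on the
#' per-level 0/1 indicator).
#'
#' @param records Coded record tibble (see [code_records()]).
#' @param attribute Column name.
#' @param kind `"continuous"`, `"categorical"`, or `"binary"`.
#' @param cluster_mask Optional logical vector selecting the cluster; NULL
#'   summarizes all rows without tests.
#' @param digits Decimal places for percentages.
#' @param alpha Significance threshold.
#' @return Tibble, one row per level (one row total for continuous/binary):
#'   `attribute`, `kind`, `level`, `n`, `count`, `pct`, `mean`, `sd`, `t`,
#'   `df`, `p`, `significant`.
#' @export
summarize_attribute <- function(records, attribute,
                                kind = c("continuous", "categorical", "binary"),
                                cluster_mask = NULL, digits = 2,
                                alpha = 0.01) {
  kind <- match.arg(kind)
  if (!attribute %in% names(records)) {
    abort_somward(paste0("no such attribute: ", attribute), "profile")
  }
  vals <- records[[attribute]]
  in_cluster <- cluster_mask %||% rep(TRUE, nrow(records))
  if (!any(in_cluster)) abort_somward("empty cluster", "profile")
  x <- vals[in_cluster]
  y <- if (is.null(cluster_mask)) NULL else vals[!in_cluster]
  n_cluster <- sum(in_cluster)

  test_or_na <- function(xv, yv) {
    if (is.null(cluster_mask)) {
      tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                     significant = NA)
    } else {
      cluster_mean_test(xv, yv, alpha = alpha)
    }
  }
  base <- tibble::tibble(attribute = attribute, kind = kind)
  if (kind == "continuous") {
    xn <- as.numeric(x)
    n_ok <- sum(!is.na(xn))
    if (n_ok == 0L) {
      return(dplyr::bind_cols(base, tibble::tibble(
        level = NA_character_, n = n_cluster, count = NA_real_,
        pct = NA_real_, mean = NA_real_, sd = NA_real_,
        t = NA_real_, df = NA_real_, p = NA_real_, significant = NA
      )))
    }
    dplyr::bind_cols(base, tibble::tibble(
      level = NA_character_, n = n_ok, count = NA_real_, pct = NA_real_,
      mean = mean(xn, na.rm = TRUE), sd = stats::sd(xn, na.rm = TRUE)
    ), test_or_na(xn, as.numeric(y)))
  } else if (kind == "binary") {
    xn <- as.numeric(x)
    cnt <- sum(xn == 1, na.rm = TRUE)
    dplyr::bind_cols(base, tibble::tibble(
      level = NA_character_, n = n_cluster, count = cnt,
      pct = binary_percent(cnt, n_cluster, digits),
      mean = mean(xn, na.rm = TRUE), sd = stats::sd(xn, na.rm = TRUE)
    ), test_or_na(xn, as.numeric(y)))
  } else {
    levels_seen <- if (is.factor(vals)) levels(vals) else {
      lv <- MCOD_LEVELS[[attribute]]
      if (is.null(lv)) sort(unique(vals[!is.na(vals)])) else lv
    }
    xc <- as.character(x)
    counts <- stats::setNames(
      vapply(levels_seen, function(l) sum(xc == l, na.rm = TRUE), numeric(1)),
      levels_seen
    )
    if (sum(counts) == 0) {
      return(dplyr::bind_cols(base, tibble::tibble(
        level = levels_seen, n = 0, count = NA_real_, pct = NA_real_,
        mean = NA_real_, sd = NA_real_, t = NA_real_, df = NA_real_,
        p = NA_real_, significant = NA
      )))
    }
    pcts <- categorical_percents(counts, digits)
    tests <- dplyr::bind_rows(lapply(levels_seen, function(l) {
      test_or_na(as.numeric(xc == l)[!is.na(xc)],
                 as.numeric(as.character(y) == l)[!is.na(y)])
    }))
    dplyr::bind_cols(
      base[rep(1, length(levels_seen)), ],
      tibble::tibble(level = pcts$level, n = sum(counts), count = pcts$count,
                     pct = pcts$pct, mean = NA_real_, sd = NA_real_),
      tests
    )
  }
}

#' Top-k most prevalent conditions or underlying causes in a cluster
#'
#' Prevalence of a condition category is the share of cluster records whose
#' condition set contains it; underlying-cause prevalence is the share of
#' records with that underlying category. Sorted descending; ties broken
#' alphabetically. If fewer than `k` distinct categories occur, all are
#' returned.
#'
#' @param coded Coded records of one cluster (see [code_records()]).
#' @param k List length (default 5).
#' @param which `"conditions"` (entity-axis categories) or `"underlying"`.
#' @param digits Decimal places of the prevalence percent (default 1, the
#'   prose-style convention).
#' @return Tibble: `rank`, `category`, `count`, `pct`.
#' @export
top_k_conditions <- function(coded, k = 5, which = c("conditions", "underlying"),
                             digits = 1) {
  which <- match.arg(which)
  n <- nrow(coded)
  if (n == 0L) abort_somward("empty cluster", "profile")
  counts <- if (which == "conditions") {
    table(unlist(coded$categories, use.names = FALSE))
  } else {
    table(coded$underlying_category[!is.na(coded$underlying_category)])
  }
  if (length(counts) == 0L) {
    return(tibble::tibble(rank = integer(0), category = character(0),
                          count = numeric(0), pct = numeric(0)))
  }
  out <- tibble::tibble(category = names(counts), count = as.numeric(counts))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$category)
  out <- utils::head(out, k)
  dplyr::mutate(out,
                rank = dplyr::row_number(),
                pct = binary_percent(.data$count, n, digits),
                .before = 1L)[, c("rank", "category", "count", "pct")]
}

#' Default attribute list for cluster profiling
#'
#' @return Named character vector: attribute -> kind.
#' @export
default_profile_attributes <- function() {
  c(age_years = "continuous", n_conditions = "continuous",
    sex = "categorical", race = "categorical", education = "categorical",
    marital = "categorical", resident_status = "categorical",
    place_of_death = "categorical", manner = "categorical",
    age_group = "categorical", multimorbid = "binary")
}

#' Profile all clusters against the whole sample
#'
#' For every cluster (ordered by size, largest first) and for the whole
#' sample (`cluster = "all"`), summarizes the configured attributes
#' ([summarize_attribute()]), tests cluster means against the complement,
#' and ranks the top-k conditions and underlying causes.
#'
#' @param coded Coded usable records.
#' @param labels Per-record cluster labels aligned with `coded` (from
#'   [label_records()]).
#' @param attributes Named vector attribute -> kind, see
#'   [default_profile_attributes()].
#' @param k_top Length of the top condition/cause lists.
#' @param alpha Significance threshold for the Welch tests.
#' @param digits Decimal places for table percentages.
#' @return A `cluster_profiles` object: `summaries` (long tibble over
#'   cluster x attribute x level), `top_conditions`, `top_underlying`,
#'   `sizes` (records per cluster, decreasing), `alpha`.
#' @export
profile_clusters <- function(coded, labels,
                             attributes = default_profile_attributes(),
                             k_top = 5, alpha = 0.01, digits = 2) {
  if (length(labels) != nrow(coded)) {
    abort_somward("labels not aligned with records", "profile")
  }
  sizes <- sort(table(labels), decreasing = TRUE)
  cluster_ids <- names(sizes)

  summarize_group <- function(id, mask) {
    rows <- dplyr::bind_rows(lapply(names(attributes), function(a) {
      summarize_attribute(coded, a, attributes[[a]],
                          cluster_mask = mask, digits = digits,
                          alpha = alpha)
    }))
    dplyr::mutate(rows, cluster = id,
                  cluster_n = if (is.null(mask)) nrow(coded) else sum(mask),
                  .before = 1L)
  }
  summaries <- dplyr::bind_rows(
    summarize_group("all", NULL),
    dplyr::bind_rows(lapply(cluster_ids, function(id) {
      summarize_group(id, labels == id)
    }))
  )
  tops <- function(which) {
    dplyr::bind_rows(lapply(c("all", cluster_ids), function(id) {
      sub <- if (id == "all") coded else coded[labels == id, , drop = FALSE]
      dplyr::mutate(top_k_conditions(sub, k_top, which), cluster = id,
                    .before = 1L)
    }))
  }
  structure(
    list(summaries = summaries,
         top_conditions = tops("conditions"),
         top_underlying = tops("underlying"),
         sizes = sizes, alpha = alpha),
    class = "cluster_profiles"
  )
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat("<cluster_profiles> ", length(x$sizes), " clusters, n = ",
      fmt_count(sum(x$sizes)), "; significance threshold p < ", x$alpha,
      "\n", sep = "")
  invisible(x)
}

#' Share of records with a condition that carry other conditions too
#'
#' Among records whose condition set contains `category`, the percentage
#' that report at least one further different condition (prose-style, 1
#' decimal by default). Used for statements like "of the deceased with
#' dementia, 87.1% also had one or more other health conditions".
#'
#' @param coded Coded records.
#' @param category Disease-category label.
#' @param digits Decimal places.
#' @return Tibble: `category`, `n_with`, `n_with_other`, `pct`.
#' @export
co_occurrence_share <- function(coded, category, digits = 1) {
  has <- vapply(coded$categories, function(v) category %in% v, logical(1))
  n_with <- sum(has)
  if (n_with == 0L) {
    abort_somward(paste0("no records carry category ", category), "profile")
  }
  n_other <- sum(has & coded$n_conditions >= 2L)
  tibble::tibble(category = category, n_with = n_with,
                 n_with_other = n_other,
                 pct = binary_percent(n_other, n_with, digits))
}

#' Render a Table-1-style population table
#'
#' One row per characteristic in the conventional order (age; sex; race;
#' education; marital status; resident status; place of death; manner of
#' death; conditions per record; multimorbidity), counts with thousands
#' separators, `n (pct%)` for categorical rows (non-missing denominators)
#' and `mean (SD)` for continuous rows.
#'
#' @param profiles A [profile_clusters()] result (its `"all"` rows are
#'   used), or the long summary tibble itself.
#' @return Tibble: `section`, `characteristic`, `display`.
#' @export
format_population_table <- function(profiles) {
  summaries <- if (inherits(profiles, "cluster_profiles")) {
    profiles$summaries
  } else {
    profiles
  }
  g <- dplyr::filter(summaries, .data$cluster == "all")
  row_of <- function(attribute, level = NULL) {
    r <- dplyr::filter(g, .data$attribute == !!attribute)
    if (!is.null(level)) r <- dplyr::filter(r, .data$level == !!level)
    r
  }
  disp_cont <- function(r) paste0(fmt_pct(r$mean, 2), " (", fmt_pct(r$sd, 2), ")")
  disp_cat <- function(r) paste0(fmt_count(r$count), " (", fmt_pct(r$pct, 2), "%)")
  out <- list()
  add <- function(section, characteristic, display) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      section = section, characteristic = characteristic, display = display
    )
  }
  add("age", "Age at death (years)", disp_cont(row_of("age_years")))
  add("sex", "Female", disp_cat(row_of("sex", "female")))
  pretty <- c(
    white = "White", black = "Black", american_indian = "American Indian",
    asian_pacific = "Asian/Pacific islander",
    primary = "Primary", secondary = "Secondary", tertiary = "Tertiary",
    married = "Married", widowed = "Widowed", divorced = "Divorced",
    never_married = "Never married",
    local = "Local Resident", nonlocal_us = "Non-Local US Resident",
    foreign = "Foreign Resident",
    hospital_inpatient = "Hospital (Inpatient)",
    hospital_outpatient_er = "Hospital (Outpatient / Emergency room)",
    hospital_doa = "Hospital (Dead on Arrival)",
    home = "Home", hospice = "Hospice Facility", nursing_home = "Nursing Home",
    other = "Other",
    accident = "Accident", suicide = "Suicide", homicide = "Homicide",
    natural = "Natural"
  )
  for (attr in c("race", "education", "marital", "resident_status",
                 "place_of_death", "manner")) {
    r <- row_of(attr)
    for (i in seq_len(nrow(r))) {
      label <- unname(pretty[r$level[i]])
      if (is.na(label)) label <- r$level[i]
      add(attr, label, disp_cat(r[i, ]))
    }
  }
  add("conditions", "Different Health Conditions associated with Death",
      disp_cont(row_of("n_conditions")))
  mm <- row_of("multimorbid")
  add("multimorbid", "Multimorbid", disp_cat(mm))
  dplyr::bind_rows(out)
}

#' Write cluster profiles to disk
#'
#' The long summary table, the two top-5 tables, and a human-readable
#' population table go to CSV/text files under `dir`.
#'
#' @param profiles A [profile_clusters()] result.
#' @param dir Output directory (created if missing).
#' @return Named vector of paths, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    summaries = file.path(dir, "cluster_summaries.csv"),
    top_conditions = file.path(dir, "top_conditions.csv"),
    top_underlying = file.path(dir, "top_underlying.csv"),
    population_table = file.path(dir, "population_table.txt")
  )
  readr::write_csv(profiles$summaries, paths[["summaries"]], progress = FALSE)
  readr::write_csv(profiles$top_conditions, paths[["top_conditions"]],
                   progress = FALSE)
  readr::write_csv(profiles$top_underlying, paths[["top_underlying"]],
                   progress = FALSE)
  tab <- format_population_table(profiles)
  writeLines(paste0(format(tab$characteristic, width = 44), tab$display),
             paths[["population_table"]])
  invisible(paths)
}
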