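#' @importFrom rlang .data
NULL

# canonical attribute levels for MCOD-like records
MCOD_LEVELS <- list(
  sex = c("female", "male"),
  race = c("white", "black", "american_indian", "asian_pacific"),
  education = c("primary", "secondary", "tertiary"),
  marital = c("married", "widowed", "divorced", "never_married"),
  resident_status = c("local", "nonlocal_us", "foreign"),
  place_of_death = c("hospital_inpatient", "hospital_outpatient_er",
                     "hospital_doa", "home", "hospice", "nursing_home",
                     "other"),
  manner = c("accident", "suicide", "homicide", "natural")
)

#' Default MCOD column schema
#'
#' Maps the canonical record fields to the column names of a delimited MCOD
#' export. `conditions` may name either a single delimited field holding all
#' entity-axis condition codes (with `conditions_sep`) or a vector of up to 20
#' positional columns.
#'
#' @param ... Overrides of individual entries, e.g. `age_years = "AGE"`.
#' @return Named list usable as the `schema` argument of [read_mcod()].
#' @export
mcod_schema <- function(...) {
  schema <- list(
    record_id = "record_id",
    data_year = "data_year",
    age_years = "age_years",
    sex = "sex",
    race = "race",
    education = "education",
    marital = "marital",
    resident_status = "resident_status",
    place_of_death = "place_of_death",
    manner = "manner",
    underlying_cause = "underlying_cause",
    conditions = "entity_conditions",
    conditions_sep = " "
  )
  utils::modifyList(schema, list(...))
}

#' Read MCOD-like death records from a delimited file
#'
#' Parses a CSV/TSV export of multiple-cause-of-death records into one row
#' per death certificate. Rows whose condition codes (or underlying cause)
#' violate ICD-10 syntax, or that carry more than 20 entity-axis codes, are
#' skipped and reported, not fatal: with tens of millions of certificates a
#' handful of malformed rows must not abort a run.
#'
#' @param path Delimited text file; the delimiter is inferred from the
#'   extension (`.tsv` = tab, otherwise comma).
#' @param schema Column schema from [mcod_schema()], or a path to a YAML file
#'   holding one.
#' @return A tibble of parsed records (`entity_conditions` is a list-column
#'   of ICD-10 code vectors) with attributes `n_parsed`, `n_malformed`, and
#'   `parse_errors` (tibble of `row`, `message`).
#' @export
read_mcod <- function(path, schema = mcod_schema()) {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- utils::modifyList(mcod_schema(), yaml::read_yaml(schema))
  }
  if (!file.exists(path)) abort_somward(paste0("no such file: ", path), "io")
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  required <- c("record_id", "underlying_cause", "conditions")
  for (field in required) {
    cols <- schema[[field]]
    if (!all(cols %in% names(raw))) {
      abort_somward(
        paste0("schema column(s) missing from file: ",
               paste(setdiff(cols, names(raw)), collapse = ", ")),
        "schema"
      )
    }
  }
  as_mcod_records(raw, schema)
}

#' Assemble raw records from a parsed data frame
#'
#' The workhorse behind [read_mcod()], exposed so in-memory tables (e.g. from
#' the synthetic generator) go through the identical validation path.
#'
#' @param raw Data frame of character columns.
#' @param schema Column schema, see [mcod_schema()].
#' @return Tibble of records; see [read_mcod()].
#' @export
as_mcod_records <- function(raw, schema = mcod_schema()) {
  n <- nrow(raw)
  get_col <- function(field) {
    col <- schema[[field]]
    if (!is.null(col) && length(col) == 1L && col %in% names(raw)) {
      as.character(raw[[col]])
    } else {
      rep(NA_character_, n)
    }
  }
  conditions_cols <- schema$conditions
  if (length(conditions_cols) > 1L) {
    cond_mat <- as.matrix(raw[, conditions_cols, drop = FALSE])
    conds <- lapply(seq_len(n), function(i) {
      v <- toupper(cond_mat[i, ])
      v[!is.na(v) & nzchar(v)]
    })
  } else {
    conds <- strsplit(
      toupper(trimws(dplyr::coalesce(as.character(raw[[conditions_cols]]), ""))),
      schema$conditions_sep %||% " ", fixed = TRUE
    )
    conds <- lapply(conds, function(v) v[nzchar(v)])
  }
  underlying <- toupper(get_col("underlying_cause"))
  age <- suppressWarnings(as.integer(get_col("age_years")))

  err_msg <- character(0)
  err_row <- integer(0)
  flag <- function(rows, msg) {
    err_row <<- c(err_row, rows)
    err_msg <<- c(err_msg, rep(msg, length(rows)))
  }
  bad_cond <- vapply(conds, function(v) length(v) > 0 && !all(is_valid_icd10(v)),
                     logical(1))
  flag(which(bad_cond), "malformed entity-axis condition code")
  too_many <- lengths(conds) > 20L
  flag(which(too_many & !bad_cond), "more than 20 entity-axis condition codes")
  bad_uc <- !is.na(underlying) & nzchar(underlying) & !is_valid_icd10(underlying)
  flag(which(bad_uc & !bad_cond & !too_many), "malformed underlying-cause code")
  bad_age <- !is.na(age) & (age < 0L | age > 130L)
  flag(which(bad_age & !bad_cond & !too_many & !bad_uc), "age outside [0, 130]")

  drop <- bad_cond | too_many | bad_uc | bad_age
  keep <- which(!drop)

  parse_level <- function(x, levels) {
    x[!is.na(x) & !x %in% levels] <- NA_character_
    x
  }
  out <- tibble::tibble(
    record_id = get_col("record_id")[keep],
    data_year = suppressWarnings(as.integer(get_col("data_year")))[keep],
    age_years = age[keep],
    sex = parse_level(get_col("sex"), MCOD_LEVELS$sex)[keep],
    race = parse_level(get_col("race"), MCOD_LEVELS$race)[keep],
    education = parse_level(get_col("education"), MCOD_LEVELS$education)[keep],
    marital = parse_level(get_col("marital"), MCOD_LEVELS$marital)[keep],
    resident_status = parse_level(get_col("resident_status"),
                                  MCOD_LEVELS$resident_status)[keep],
    place_of_death = parse_level(get_col("place_of_death"),
                                 MCOD_LEVELS$place_of_death)[keep],
    manner = parse_level(get_col("manner"), MCOD_LEVELS$manner)[keep],
    underlying_cause = ifelse(nzchar(underlying) & !is.na(underlying),
                              underlying, NA_character_)[keep],
    entity_conditions = conds[keep]
  )
  attr(out, "n_parsed") <- n
  attr(out, "n_malformed") <- sum(drop)
  attr(out, "parse_errors") <- tibble::tibble(row = err_row, message = err_msg)
  out
}

#' Default age bands
#'
#' Cut points for the derived `age_group`: under 18, 18-40, 41-64, 65-84,
#' and 85 plus — the bands used when tabulating deaths of children, younger
#' adults and the very old.
#' @return Named integer vector of lower band edges.
#' @export
default_age_breaks <- function() c(0L, 18L, 41L, 65L, 85L)

age_band_labels <- function(breaks) {
  upper <- c(breaks[-1] - 1L, NA)
  ifelse(is.na(upper), paste0(breaks, "+"),
         ifelse(breaks == 0L, paste0("<", upper + 1L),
                paste0(breaks, "-", upper)))
}

#' Code parsed records into disease categories
#'
#' Applies the category map to every entity-axis condition code, deduplicates
#' categories within the record ("different health conditions"), maps the
#' underlying cause separately (it is not force-added to the condition set),
#' derives the multimorbidity indicator — 1 when the record carries two or
#' more different disease categories, 0 otherwise — and the age band.
#'
#' @param records Tibble from [read_mcod()] / [as_mcod_records()].
#' @param map A [category_map()].
#' @param age_breaks Lower edges of the age bands, see [default_age_breaks()].
#' @return The input tibble plus `categories` (list-column, deduplicated,
#'   sorted), `n_conditions`, `multimorbid` (integer 0/1),
#'   `underlying_category`, and `age_group`.
#' @export
code_records <- function(records, map, age_breaks = default_age_breaks()) {
  stopifnot(inherits(map, "category_map"))
  conds <- records$entity_conditions
  lens <- lengths(conds)
  flat <- unlist(conds, use.names = FALSE)
  flat_cat <- if (length(flat)) map_code_to_category(flat, map) else character(0)
  idx <- rep.int(seq_along(conds), lens)
  cats <- vector("list", length(conds))
  cats[] <- list(character(0))
  if (length(flat_cat)) {
    split_cats <- split(flat_cat, idx)
    cats[as.integer(names(split_cats))] <-
      lapply(split_cats, function(v) sort(unique(v)))
  }
  n_cond <- lengths(cats)
  uc <- records$underlying_cause
  uc_cat <- rep(NA_character_, length(uc))
  ok <- !is.na(uc)
  if (any(ok)) uc_cat[ok] <- map_code_to_category(uc[ok], map)

  labels <- age_band_labels(age_breaks)
  band <- findInterval(records$age_years, age_breaks)
  age_group <- ifelse(is.na(band) | band == 0L, NA_character_, labels[band])

  dplyr::mutate(
    records,
    categories = cats,
    n_conditions = n_cond,
    multimorbid = as.integer(n_cond >= 2L),
    underlying_category = uc_cat,
    age_group = factor(age_group, levels = labels)
  )
}

#' Drop records with no recorded health conditions
#'
#' Records without any entity-axis health condition carry no clustering
#' signal and are omitted, mirroring the study bookkeeping: usable records +
#' omitted records = parsed records.
#'
#' @param coded Tibble from [code_records()].
#' @return Tibble of usable records (`n_conditions >= 1`) with attribute
#'   `omitted_count`.
#' @export
filter_usable <- function(coded) {
  usable <- dplyr::filter(coded, .data$n_conditions >= 1L)
  attr(usable, "omitted_count") <- nrow(coded) - nrow(usable)
  usable
}

#' Build the binary disease-category indicator matrix
#'
#' Row i, column j is 1 exactly when record i carries category j; the row sum
#' equals the record's number of different health conditions, so
#' `multimorbid == (rowSums(M) >= 2)`.
#'
#' @param coded Tibble from [code_records()] (usually after [filter_usable()]).
#' @param vocabulary Category vocabulary fixing column order (typically
#'   `map$vocabulary`).
#' @return Integer matrix, `nrow(coded)` x `length(vocabulary)`, dimnames =
#'   record ids x categories.
#' @export
build_indicator_matrix <- function(coded, vocabulary) {
  cats <- coded$categories
  lens <- lengths(cats)
  flat <- unlist(cats, use.names = FALSE)
  col <- match(flat, vocabulary)
  if (anyNA(col)) {
    abort_somward(
      paste0("categories outside the vocabulary: ",
             paste(unique(flat[is.na(col)]), collapse = ", ")),
      "vocab"
    )
  }
  m <- matrix(0L, nrow = nrow(coded), ncol = length(vocabulary),
              dimnames = list(coded$record_id, vocabulary))
  if (length(flat)) m[cbind(rep.int(seq_len(nrow(coded)), lens), col)] <- 1L
  m
}

#' Write coded records back to CSV
#'
#' The list-columns are flattened: categories and entity codes become
#' space-delimited strings, so the file round-trips through [read_mcod()].
#'
#' @param coded Tibble from [code_records()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coded_records <- function(coded, path) {
  out <- dplyr::mutate(
    coded,
    entity_conditions = vapply(.data$entity_conditions, paste, "",
                               collapse = " "),
    categories = vapply(.data$categories, paste, "", collapse = " ")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
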