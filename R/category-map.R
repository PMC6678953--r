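#' Build a disease-category map
#'
#' A category map aggregates ICD-10 codes into disease categories by prefix
#' rules: a code belongs to the category of the longest rule prefix that
#' matches it, with ties between equal-length prefixes broken by rule order.
#' The full study configuration carries 346 categories; the map is supplied by
#' the user as data, and [demo_category_map()] ships a reduced 32-category
#' version for examples and tests.
#'
#' @param rules Data frame with columns `prefix` (ICD-10 code prefix, 1-5
#'   characters) and `label` (target category). Rule order is meaningful.
#' @param vocabulary Optional character vector fixing the category vocabulary
#'   and its column order in indicator matrices. Defaults to the labels in
#'   rule order. Must contain every rule label.
#' @param fallback How to treat a syntactically valid code matched by no rule:
#'   `"other_bucket"` maps it to `"other"` (appended to the vocabulary if
#'   absent), `"error"` raises an unmapped-code error.
#' @return An object of class `category_map`.
#' @seealso [map_code_to_category()], [read_category_map()]
#' @export
category_map <- function(rules, vocabulary = NULL,
                         fallback = c("other_bucket", "error")) {
  fallback <- match.arg(fallback)
  rules <- tibble::as_tibble(rules)
  stopifnot(all(c("prefix", "label") %in% names(rules)))
  rules$prefix <- toupper(as.character(rules$prefix))
  rules$label <- as.character(rules$label)
  if (any(!grepl("^[A-Z][0-9A-Z]{0,4}$", rules$prefix))) {
    abort_somward("category map prefixes must start with a letter", "map")
  }
  vocabulary <- vocabulary %||% unique(rules$label)
  missing <- setdiff(rules$label, vocabulary)
  if (length(missing)) {
    abort_somward(
      paste0("rule labels not in vocabulary: ", paste(missing, collapse = ", ")),
      "map"
    )
  }
  if (fallback == "other_bucket" && !"other" %in% vocabulary) {
    vocabulary <- c(vocabulary, "other")
  }
  structure(
    list(rules = rules, vocabulary = vocabulary, fallback = fallback),
    class = "category_map"
  )
}

#' @export
print.category_map <- function(x, ...) {
  cat("<category_map> ", nrow(x$rules), " rules -> ",
      length(x$vocabulary), " categories (fallback: ", x$fallback, ")\n",
      sep = "")
  invisible(x)
}

#' Read a category map from CSV or YAML
#'
#' CSV maps have columns `prefix,label`; YAML maps have a `rules` list of
#' `{prefix, label}` entries and optional `vocabulary` and `fallback` keys.
#'
#' @param path File path (`.csv`, `.yaml`/`.yml`).
#' @inheritParams category_map
#' @return A `category_map`.
#' @export
read_category_map <- function(path, fallback = c("other_bucket", "error")) {
  fallback <- match.arg(fallback)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    rules <- dplyr::bind_rows(lapply(y$rules, tibble::as_tibble))
    category_map(rules,
                 vocabulary = y$vocabulary,
                 fallback = y$fallback %||% fallback)
  } else {
    rules <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
    category_map(rules, fallback = fallback)
  }
}

#' Map ICD-10 codes to disease categories
#'
#' Longest-prefix match against the map's rules; ties between rules with
#' equal-length prefixes are broken by rule order. Deterministic: the same
#' code always yields the same label.
#'
#' @param code Character vector of syntactically valid ICD-10 codes.
#' @param map A [category_map()].
#' @return Character vector of category labels, same length as `code`.
#' @examples
#' m <- demo_category_map()
#' map_code_to_category(c("I251", "C349", "J440"), m)
#' @export
map_code_to_category <- function(code, map) {
  stopifnot(inherits(map, "category_map"))
  code <- toupper(code)
  bad <- !is_valid_icd10(code)
  if (any(bad)) {
    abort_somward(
      paste0("syntactically invalid ICD-10 code(s): ",
             paste(unique(code[bad]), collapse = ", ")),
      "icd"
    )
  }
  out <- rep(NA_character_, length(code))
  lens <- sort(unique(nchar(map$rules$prefix)), decreasing = TRUE)
  for (L in lens) {
    todo <- is.na(out)
    if (!any(todo)) break
    sub <- map$rules[nchar(map$rules$prefix) == L, ]
    # match() returns the first hit, preserving rule order for ties
    hit <- match(substr(code[todo], 1L, L), sub$prefix)
    out[todo] <- sub$label[hit]
  }
  if (anyNA(out)) {
    if (map$fallback == "error") {
      abort_somward(
        paste0("unmapped ICD-10 code(s): ",
               paste(unique(code[is.na(out)]), collapse = ", ")),
        "unmapped"
      )
    }
    out[is.na(out)] <- "other"
  }
  out
}

#' Reduced demonstration category map
#'
#' A 49-category map covering the disease categories that drive the study's
#' named clusters (atherosclerotic heart disease, cardiac arrest,
#' hypertension, heart failure, COPD, pneumonia, dementia, sepsis, the major
#' cancers, external causes, ...) plus the common comorbid conditions seen
#' on death certificates (atrial fibrillation, chronic kidney disease,
#' anemia, pressure ulcers, ...). The full 346-category aggregation table is
#' a user-supplied configuration; this demo map keeps the pipeline runnable
#' and testable without it. Prefix rules are illustrative, not a complete
#' ICD-10 partition.
#'
#' @return A `category_map` with 49 categories (including the `other` bucket).
#' @export
demo_category_map <- function() {
  rules <- tibble::tribble(
    ~prefix, ~label,
    "I25", "atherosclerotic_heart_disease",
    "I46", "cardiac_arrest",
    "I10", "hypertension",
    "I11", "hypertensive_heart_disease",
    "I21", "myocardial_infarction",
    "I48", "atrial_fibrillation",
    "I50", "heart_failure",
    "I61", "cerebral_hemorrhage",
    "I64", "unspecified_stroke",
    "R57", "cardiogenic_shock",
    "J44", "copd",
    "J12", "pneumonia",
    "J13", "pneumonia",
    "J14", "pneumonia",
    "J15", "pneumonia",
    "J18", "pneumonia",
    "J69", "pneumonitis",
    "J84", "interstitial_lung_disease",
    "J90", "pleural_effusion",
    "J91", "pleural_effusion",
    "J96", "respiratory_failure",
    "F01", "dementia",
    "F03", "dementia",
    "G30", "dementia",
    "G20", "neurodegenerative_disease",
    "G12", "neurodegenerative_disease",
    "G81", "hemiplegia",
    "F10", "alcohol_abuse",
    "F11", "drug_abuse",
    "F19", "drug_abuse",
    "F17", "nicotine_dependence",
    "A41", "other_sepsis",
    "A40", "other_sepsis",
    "B99", "other_infection",
    "N39", "urinary_tract_infection",
    "E10", "diabetes_mellitus",
    "E11", "diabetes_mellitus",
    "E14", "diabetes_mellitus",
    "E66", "obesity",
    "E78", "hyperlipidemia",
    "D64", "anemia",
    "L89", "pressure_ulcer",
    "M80", "osteoporosis",
    "M81", "osteoporosis",
    "N17", "kidney_failure",
    "N19", "kidney_failure",
    "N18", "chronic_kidney_disease",
    "C50", "breast_cancer",
    "C61", "prostate_cancer",
    "C34", "lung_cancer",
    "C85", "non_hodgkin_lymphoma",
    "C78", "secondary_malignancy",
    "C79", "secondary_malignancy",
    "C15", "gastrointestinal_cancer",
    "C16", "gastrointestinal_cancer",
    "C18", "gastrointestinal_cancer",
    "C25", "gastrointestinal_cancer",
    "C", "other_cancer",
    "K70", "liver_disease",
    "K74", "liver_disease",
    "K92", "gastrointestinal_disease",
    "K56", "gastrointestinal_disease",
    "T39", "poisoning",
    "T50", "poisoning",
    "X4", "poisoning",
    "T14", "open_wound",
    "S06", "traumatic_brain_injury",
    "S0", "open_wound",
    "S72", "fracture",
    "T71", "suffocation",
    "W", "other_physical_harm",
    "Y", "other_physical_harm"
  )
  category_map(rules, fallback = "other_bucket")
}

#' One representative ICD-10 code per demo category
#'
#' Used by the synthetic generator, which simulates at disease-category level
#' and emits one representative code per category so that generated files
#' round-trip through the ingest coding path.
#'
#' @return Named character vector: category label -> ICD-10 code.
#' @export
demo_representative_codes <- function() {
  c(
    atherosclerotic_heart_disease = "I251",
    cardiac_arrest = "I469",
    hypertension = "I10",
    hypertensive_heart_disease = "I119",
    myocardial_infarction = "I219",
    atrial_fibrillation = "I489",
    heart_failure = "I509",
    cerebral_hemorrhage = "I619",
    unspecified_stroke = "I64",
    cardiogenic_shock = "R570",
    copd = "J449",
    pneumonia = "J189",
    pneumonitis = "J690",
    interstitial_lung_disease = "J849",
    pleural_effusion = "J90",
    respiratory_failure = "J969",
    dementia = "G309",
    neurodegenerative_disease = "G20",
    hemiplegia = "G819",
    alcohol_abuse = "F102",
    drug_abuse = "F199",
    nicotine_dependence = "F179",
    other_sepsis = "A419",
    other_infection = "B99",
    urinary_tract_infection = "N390",
    diabetes_mellitus = "E149",
    obesity = "E669",
    hyperlipidemia = "E785",
    anemia = "D649",
    pressure_ulcer = "L89",
    osteoporosis = "M819",
    kidney_failure = "N19",
    chronic_kidney_disease = "N189",
    breast_cancer = "C509",
    prostate_cancer = "C61",
    lung_cancer = "C349",
    non_hodgkin_lymphoma = "C859",
    secondary_malignancy = "C798",
    gastrointestinal_cancer = "C189",
    other_cancer = "C80",
    liver_disease = "K746",
    gastrointestinal_disease = "K922",
    poisoning = "T509",
    open_wound = "T14",
    traumatic_brain_injury = "S069",
    fracture = "S720",
    suffocation = "T71",
    other_physical_harm = "W74",
    other = "R99"
  )
}
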