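#' Default synthetic benchmark population
#'
#' A 16-cluster latent-class population over the 49-category demo
#' vocabulary, used throughout the tests and the reproduction script. Each
#' chronic-disease cluster carries a disjoint triple of signature conditions
#' (prevalences about 0.95 / 0.80 / 0.50) on top of a low background
#' prevalence, so clusters are well separated in indicator space; three
#' external-cause clusters (poisoning, open wound/suffocation, other
#' physical harm) and one acute cardiac cluster have near-single-condition
#' profiles, and the external clusters young age distributions and
#' non-natural manners of death.
#'
#' The mixture is calibrated so that, at `n = 100,000`, the generated
#' margins land on the gross margins of US multiple-cause-of-death data:
#' mean conditions per record about 3.0, multimorbidity (>= 2 different
#' conditions) about 78%, and mean age at death about 73 years.
#'
#' @param n_records Population size (default 100,000).
#' @param seed Default seed stored in the spec.
#' @return A [population_spec()] with 16 clusters.
#' @export
default_benchmark_spec <- function(n_records = 100000L, seed = 20060101L) {
  vocab <- demo_category_map()$vocabulary

  base <- list(
    sex = c(female = 0.4976, male = 0.5024),
    race = c(white = 0.8550, black = 0.1168, american_indian = 0.0064,
             asian_pacific = 0.0219),
    education = c(primary = 0.1329, secondary = 0.5465, tertiary = 0.3206),
    marital = c(married = 0.3802, widowed = 0.3536, divorced = 0.1443,
                never_married = 0.1219),
    resident = c(local = 0.8089, nonlocal_us = 0.1893, foreign = 0.0018),
    place = c(hospital_inpatient = 0.3261, hospital_outpatient_er = 0.0676,
              hospital_doa = 0.0060, home = 0.2779, hospice = 0.0530,
              nursing_home = 0.2066, other = 0.0629),
    manner_natural = c(accident = 0.005, suicide = 0.001, homicide = 0.001,
                       natural = 0.993)
  )
  tweak <- function(p, ...) {
    adj <- c(...)
    p[names(adj)] <- adj
    p / sum(p)
  }
  prev <- function(signatures, background) {
    v <- stats::setNames(rep(background, length(vocab)), vocab)
    v[names(signatures)] <- signatures
    v
  }
  disease <- function(label, weight, signatures, age_mean,
                      background = 0.03, age_sd = 13, ...) {
    args <- list(
      label = label, weight = weight,
      condition_prevalence = prev(signatures, background),
      age_mean = age_mean, age_sd = age_sd,
      sex_probs = base$sex, race_probs = base$race,
      education_probs = base$education, marital_probs = base$marital,
      resident_probs = base$resident, place_probs = base$place,
      manner_probs = base$manner_natural
    )
    overrides <- list(...)
    args[names(overrides)] <- overrides
    do.call(cluster_spec, args)
  }
  external <- function(label, weight, signatures, age_mean, manner_probs) {
    cluster_spec(
      label = label, weight = weight,
      condition_prevalence = prev(signatures, background = 0.004),
      age_mean = age_mean, age_sd = 15,
      sex_probs = tweak(base$sex, male = 0.70, female = 0.30),
      race_probs = base$race,
      education_probs = tweak(base$education, primary = 0.08,
                              secondary = 0.62, tertiary = 0.30),
      marital_probs = tweak(base$marital, never_married = 0.38,
                            married = 0.30, widowed = 0.10,
                            divorced = 0.22),
      resident_probs = base$resident,
      place_probs = tweak(base$place, home = 0.35, other = 0.25,
                          hospital_inpatient = 0.20,
                          hospital_outpatient_er = 0.12, hospital_doa = 0.04,
                          hospice = 0.01, nursing_home = 0.03),
      manner_probs = manner_probs
    )
  }
  sig <- function(primary, secondary, tertiary,
                  p = c(0.95, 0.80, 0.50)) {
    stats::setNames(p, c(primary, secondary, tertiary))
  }

  clusters <- list(
    disease("cardiovascular", 0.1446,
            sig("heart_failure", "atherosclerotic_heart_disease",
                "atrial_fibrillation"),
            age_mean = 87,
            place_probs = tweak(base$place, hospital_inpatient = 0.435,
                                home = 0.286)),
    disease("other_cancer", 0.1021,
            sig("other_cancer", "breast_cancer", "secondary_malignancy"),
            age_mean = 74,
            marital_probs = tweak(base$marital, married = 0.50,
                                  widowed = 0.24),
            place_probs = tweak(base$place, home = 0.40, hospice = 0.10,
                                nursing_home = 0.12)),
    disease("uro_gi_infection", 0.0936,
            sig("other_sepsis", "kidney_failure", "urinary_tract_infection"),
            age_mean = 84,
            place_probs = tweak(base$place, hospital_inpatient = 0.584,
                                home = 0.12, nursing_home = 0.12)),
    disease("respiratory", 0.0766,
            sig("copd", "pneumonia", "respiratory_failure"), age_mean = 82,
            education_probs = tweak(base$education, tertiary = 0.22,
                                    secondary = 0.60, primary = 0.18),
            place_probs = tweak(base$place, hospital_inpatient = 0.466)),
    disease("geriatric", 0.0553,
            sig("dementia", "pneumonitis", "pressure_ulcer"), age_mean = 89,
            sex_probs = c(female = 0.65, male = 0.35),
            marital_probs = tweak(base$marital, widowed = 0.58,
                                  married = 0.20),
            place_probs = tweak(base$place, nursing_home = 0.504,
                                hospital_inpatient = 0.18, home = 0.15)),
    disease("hypertensive", 0.0357,
            sig("hypertension", "hypertensive_heart_disease",
                "hyperlipidemia"), age_mean = 84),
    disease("stroke", 0.0357,
            sig("unspecified_stroke", "cerebral_hemorrhage", "hemiplegia"),
            age_mean = 86,
            race_probs = tweak(base$race, asian_pacific = 0.045)),
    disease("lung_cancer", 0.0357,
            sig("lung_cancer", "nicotine_dependence", "pleural_effusion"),
            age_mean = 72,
            marital_probs = tweak(base$marital, married = 0.49),
            place_probs = tweak(base$place, home = 0.44, hospice = 0.09)),
    disease("gi_cancer", 0.0357,
            sig("gastrointestinal_cancer", "non_hodgkin_lymphoma", "anemia"),
            age_mean = 74,
            marital_probs = tweak(base$marital, married = 0.49),
            race_probs = tweak(base$race, asian_pacific = 0.04),
            place_probs = tweak(base$place, home = 0.45)),
    disease("liver", 0.0340,
            sig("liver_disease", "gastrointestinal_disease", "alcohol_abuse"),
            age_mean = 68,
            race_probs = tweak(base$race, american_indian = 0.025),
            place_probs = tweak(base$place, hospital_inpatient = 0.45)),
    disease("diabetes_renal", 0.0340,
            sig("diabetes_mellitus", "chronic_kidney_disease", "obesity"),
            age_mean = 79),
    disease("prostate_cancer", 0.0298,
            sig("prostate_cancer", "interstitial_lung_disease",
                "osteoporosis"), age_mean = 82,
            sex_probs = c(female = 0.02, male = 0.98)),
    # acute cardiac: near-single-condition but natural manner
    disease("cardiac_acute", 0.0372,
            sig("cardiac_arrest", "myocardial_infarction",
                "cardiogenic_shock", p = c(0.97, 0.25, 0.10)),
            age_mean = 81, background = 0.008,
            place_probs = tweak(base$place, hospital_doa = 0.05,
                                hospital_outpatient_er = 0.18, home = 0.33)),
    external("poisoning", 0.09,
             sig("poisoning", "drug_abuse", "other", p = c(0.98, 0.08, 0.05)),
             age_mean = 46,
             manner_probs = c(accident = 0.62, suicide = 0.30,
                              homicide = 0.02, natural = 0.06)),
    external("open_wound_suffocation", 0.09,
             sig("open_wound", "suffocation", "traumatic_brain_injury",
                 p = c(0.95, 0.30, 0.10)),
             age_mean = 48,
             manner_probs = c(accident = 0.40, suicide = 0.35,
                              homicide = 0.23, natural = 0.02)),
    external("other_physical_harm", 0.07,
             sig("other_physical_harm", "fracture", "other",
                 p = c(0.98, 0.08, 0.05)),
             age_mean = 54,
             manner_probs = c(accident = 0.75, suicide = 0.12,
                              homicide = 0.08, natural = 0.05))
  )
  population_spec(n_records = n_records, clusters = clusters, seed = seed)
}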