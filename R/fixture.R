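#' The built-in pre-anesthesia cohort schema
#'
#' A fixed 85-feature layout emulating a pre-anesthesia assessment cohort:
#' 19 numerical vitals/labs/anthropometrics, 60 binary comorbidity, medication
#' and history flags, and 6 four-level categorical assessments (ASA class,
#' functional capacity in METs, Mallampati class, smoking status, anesthesia
#' type, surgical risk). Its encoded design-matrix width is 19 + 60 + 6*4 =
#' 103 columns. The feature list is synthetic — clinically plausible names and
#' ranges, with no claim of matching any real cohort's variables.
#'
#' @return A [cohort_schema()] with 85 columns.
#' @examples
#' encoded_width(fixture_schema()) # 103
#' @export
fixture_schema <- function() {
  numerics <- tibble::tribble(
    ~name, ~min, ~max, ~int,
    "age",                18,   95,  TRUE,
    "weight_kg",          40,  160,  FALSE,
    "height_cm",         140,  210,  FALSE,
    "bmi",                 9,   82,  FALSE,
    "sbp_mmhg",           80,  220,  TRUE,
    "dbp_mmhg",           40,  130,  TRUE,
    "heart_rate_bpm",     40,  140,  TRUE,
    "spo2_pct",           80,  100,  TRUE,
    "hemoglobin_g_dl",     7,   19,  FALSE,
    "creatinine_umol_l",  30,  400,  FALSE,
    "glucose_mmol_l",      3,   20,  FALSE,
    "albumin_g_l",        20,   55,  FALSE,
    "egfr_ml_min",        15,  120,  FALSE,
    "crp_mg_l",            0,  150,  FALSE,
    "platelets_g_l",      50,  600,  TRUE,
    "sodium_mmol_l",     125,  150,  TRUE,
    "potassium_mmol_l",  2.5,  6.5,  FALSE,
    "alcohol_units_week",  0,   60,  TRUE,
    "pack_years",          0,   80,  TRUE
  )
  num_specs <- purrr::pmap(numerics, function(name, min, max, int) {
    col_numeric(name, min, max, integer_valued = int)
  })
  bin_names <- c(
    "sex_male", "hypertension", "diabetes", "copd", "asthma",
    "coronary_artery_disease", "heart_failure", "atrial_fibrillation",
    "chronic_kidney_disease", "stroke_history", "cancer_history",
    "current_smoker", "obstructive_sleep_apnea", "gerd", "hypothyroidism",
    "anemia", "depression", "anxiety", "arthritis", "osteoporosis",
    "liver_disease", "epilepsy", "parkinson_disease", "dementia",
    "peripheral_vascular_disease", "valvular_heart_disease", "pacemaker",
    "dialysis", "immunosuppressed", "bleeding_disorder",
    "allergy_penicillin", "allergy_latex", "allergy_iodine", "allergy_nsaid",
    "med_betablocker", "med_ace_inhibitor", "med_statin", "med_anticoagulant",
    "med_antiplatelet", "med_insulin", "med_metformin", "med_diuretic",
    "med_ppi", "med_ssri", "med_opioid", "med_benzodiazepine",
    "med_corticosteroid", "med_bronchodilator", "med_thyroid_hormone",
    "med_antiarrhythmic", "prior_general_anesthesia", "prior_surgery",
    "difficult_airway_history", "ponv_history", "motion_sickness",
    "dental_prosthesis", "loose_teeth", "contact_lenses",
    "family_anesthesia_complication", "transfusion_refusal"
  )
  bin_specs <- purrr::map(bin_names, function(nm) col_binary(nm, c("no", "yes")))
  cat_specs <- list(
    col_categorical("asa_class", c("I", "II", "III", "IV")),
    col_categorical("met_category", c("lt4", "4to6", "6to10", "gt10")),
    col_categorical("mallampati_class", c("I", "II", "III", "IV")),
    col_categorical("smoking_status", c("never", "former", "light", "heavy")),
    col_categorical("anesthesia_type", c("general", "regional", "sedation", "combined")),
    col_categorical("surgical_risk", c("low", "intermediate", "high", "major"))
  )
  cohort_schema(dplyr::bind_rows(c(num_specs, bin_specs, cat_specs)))
}

#' Configuration for the synthetic cohort generator
#'
#' The generator draws, for each patient, `latent_factors` standard-normal
#' factor scores; numerics are affine transforms of factor combinations plus
#' independent noise (clipped to their clinical ranges, BMI derived from
#' weight and height), binary flags follow a logistic model on the factors
#' calibrated to the given base prevalences, and categorical assessments
#' follow a softmax over factor scores. The factor construction gives the
#' cohort a correlation structure the fidelity audit can meaningfully test.
#'
#' @param n_patients Cohort size (default 521).
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @param latent_factors Number of latent factors k (default 4).
#' @param loadings Optional 19 x k numeric matrix of per-numeric factor
#'   loadings, rows in [fixture_schema()] numeric order, each row with squared
#'   norm < 1 (the remainder is independent noise). Default: a block pattern
#'   tying cardiometabolic, frailty, inflammation/renal and lifestyle
#'   variables to one factor each. The BMI row is ignored (BMI is derived).
#' @param binary_prevalences Optional length-60 vector of base rates in
#'   [0.02, 0.5] for the binary flags.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_patients = 521, seed = 1, latent_factors = 4,
                           loadings = NULL, binary_prevalences = NULL) {
  stopifnot(n_patients >= 0, latent_factors >= 1)
  k <- latent_factors
  if (is.null(loadings)) {
    loadings <- matrix(0, 19, k)
    # factor 1 cardiometabolic, 2 frailty/age, 3 inflammation/renal, 4 lifestyle
    blk <- function(j) ((j - 1L) %% k) + 1L
    loadings[1, blk(2)] <- 0.80   # age
    loadings[2, blk(1)] <- 0.65   # weight
    loadings[3, blk(1)] <- -0.20  # height (weak)
    # row 4 = bmi, derived
    loadings[5, blk(1)] <- 0.70   # sbp
    loadings[6, blk(1)] <- 0.60   # dbp
    loadings[7, blk(4)] <- 0.45   # heart rate
    loadings[8, blk(2)] <- -0.40  # spo2
    loadings[9, blk(3)] <- -0.45  # hemoglobin
    loadings[10, blk(3)] <- 0.75  # creatinine
    loadings[11, blk(1)] <- 0.55  # glucose
    loadings[12, blk(3)] <- -0.50 # albumin
    loadings[13, blk(3)] <- -0.80 # egfr
    loadings[14, blk(3)] <- 0.60  # crp
    loadings[15, blk(3)] <- -0.25 # platelets
    loadings[16, blk(3)] <- -0.30 # sodium
    loadings[17, blk(3)] <- 0.40  # potassium
    loadings[18, blk(4)] <- 0.75  # alcohol
    loadings[19, blk(4)] <- 0.80  # pack years
  }
  stopifnot(nrow(loadings) == 19, ncol(loadings) == k,
            all(rowSums(loadings^2) < 1))
  if (is.null(binary_prevalences)) {
    binary_prevalences <- rep(
      c(0.49, 0.35, 0.15, 0.08, 0.10, 0.12, 0.05, 0.07, 0.06, 0.04,
        0.09, 0.22, 0.08, 0.18, 0.10, 0.07, 0.14, 0.16, 0.20, 0.06),
      3
    )[seq_len(60)]
  }
  stopifnot(length(binary_prevalences) == 60,
            all(binary_prevalences >= 0.02), all(binary_prevalences <= 0.5))
  structure(
    list(n_patients = n_patients, seed = seed, latent_factors = k,
         loadings = loadings, binary_prevalences = binary_prevalences),
    class = "fixture_config"
  )
}

# means/sds on the standardized scale for the 19 fixture numerics
fixture_numeric_moments <- function() {
  tibble::tribble(
    ~name, ~mu, ~sd,
    "age",                55,  16,
    "weight_kg",          78,  16,
    "height_cm",         170,   9,
    "bmi",               NA,   NA,   # derived
    "sbp_mmhg",          132,  17,
    "dbp_mmhg",           78,  11,
    "heart_rate_bpm",     74,  12,
    "spo2_pct",           97, 1.8,
    "hemoglobin_g_dl",  13.8, 1.6,
    "creatinine_umol_l",  85,  35,
    "glucose_mmol_l",    5.8, 1.6,
    "albumin_g_l",        41,   5,
    "egfr_ml_min",        82,  20,
    "crp_mg_l",           12,  18,
    "platelets_g_l",     255,  70,
    "sodium_mmol_l",     140, 3.2,
    "potassium_mmol_l",  4.2, 0.45,
    "alcohol_units_week",  6,   9,
    "pack_years",          9,  14
  )
}

#' Draw a synthetic pre-anesthesia cohort
#'
#' @param config A [fixture_config()].
#' @return A schema-conforming tibble with `config$n_patients` rows and the 85
#'   columns of [fixture_schema()].
#' @examples
#' cohort <- simulate_cohort(fixture_config(n_patients = 50, seed = 7))
#' dim(cohort)
#' @export
simulate_cohort <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  schema <- fixture_schema()
  n <- config$n_patients
  if (n == 0L) {
    return(validate_cohort(
      stats::setNames(
        as.data.frame(purrr::map(seq_len(nrow(schema)), function(i) {
          if (schema$kind[i] == "numerical") numeric(0) else character(0)
        }), optional = TRUE),
        schema$name
      ),
      schema
    ))
  }
  set.seed(config$seed)
  k <- config$latent_factors
  f <- matrix(stats::rnorm(n * k), n, k)

  mom <- fixture_numeric_moments()
  lam <- config$loadings
  num <- matrix(NA_real_, n, 19)
  for (j in seq_len(19)) {
    if (mom$name[j] == "bmi") next
    resid_sd <- sqrt(1 - sum(lam[j, ]^2))
    z <- drop(f %*% lam[j, ]) + stats::rnorm(n, sd = resid_sd)
    spec <- schema[schema$name == mom$name[j], ]
    num[, j] <- pmin(pmax(mom$mu[j] + mom$sd[j] * z, spec$min), spec$max)
  }
  # measurement noise capped so derived BMI stays within 0.5 units of w/h^2
  bmi_noise <- pmin(pmax(stats::rnorm(n, sd = 0.15), -0.45), 0.45)
  bmi_raw <- num[, 2] / (num[, 3] / 100)^2 + bmi_noise
  num[, 4] <- pmin(pmax(bmi_raw, 9), 82)

  prev <- config$binary_prevalences
  bin <- matrix(NA_character_, n, 60)
  for (j in seq_len(60)) {
    w <- 0.9 * sin(j + seq_len(k))          # fixed, varied factor weights
    eta <- stats::qlogis(prev[j]) + drop(f %*% w)
    bin[, j] <- c("no", "yes")[1L + stats::rbinom(n, 1L, stats::plogis(eta))]
  }

  cat_cols <- schema$name[schema$kind == "categorical"]
  cats <- matrix(NA_character_, n, length(cat_cols))
  for (j in seq_along(cat_cols)) {
    lev <- schema$levels[schema$name == cat_cols[j]][[1L]]
    # level scores: graded response on one factor + fixed intercepts
    w <- 0.8 * cos(j + seq_len(k))
    eta <- drop(f %*% w)
    alpha <- c(0.6, 0.9, 0.2, -0.6)
    scores <- outer(eta, c(-1, -0.3, 0.3, 1)) + rep(alpha, each = n)
    p <- exp(scores - apply(scores, 1, max))
    p <- p / rowSums(p)
    u <- stats::runif(n)
    idx <- pmin(rowSums(u > t(apply(p, 1, cumsum))) + 1L, length(lev))
    cats[, j] <- lev[idx]
  }

  raw <- tibble::as_tibble(as.data.frame(num))
  names(raw) <- mom$name
  raw[schema$name[schema$kind == "binary"]] <- as.data.frame(bin)
  raw[cat_cols] <- as.data.frame(cats)
  validate_cohort(raw[schema$name], schema)
}

#' Resample a fresh cohort from the same generative law
#'
#' Used as the same-distribution oracle when calibrating the fidelity audit:
#' two independent draws from the same law should score near-perfect fidelity
#' and share essentially no exact duplicates.
#'
#' @param config A [fixture_config()] (its `seed` is ignored).
#' @param n Number of patients to draw.
#' @param seed Seed for the fresh draw.
#' @return A schema-conforming tibble with `n` rows.
#' @export
resample_cohort <- function(config, n, seed) {
  stopifnot(n >= 1)
  config$n_patients <- n
  config$seed <- seed
  simulate_cohort(config)
}
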