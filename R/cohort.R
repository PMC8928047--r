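# Synthetic cohort generation: a seeded emulation of the metabolic-obesity
# phenotype structure of the adult survey cohort the analysis was designed
# for (ages 30-74, six phenotypes, per-phenotype biomarker profiles).

PHENOTYPES <- c("MHNW", "MHOW", "MHO", "MUNW", "MUOW", "MUO")
AGE_GROUP_LEVELS <- c("30-39", "40-49", "50-59", "60-69", "70+")

#' Default per-phenotype biomarker profiles
#'
#' Mean/SD of each continuous biomarker within each of the six
#' metabolic-obesity phenotypes, mirroring the descriptive profile of the
#' reference cohort (units: height cm, BMI kg/m2, waist/hip cm, lipids and
#' glucose mmol/L, blood pressure mm Hg, uric acid umol/L, hsCRP mg/L,
#' HbA1c %). Creatinine (mg/dL) is profiled by sex, not phenotype.
#'
#' @return named list: one `data.frame(mean, sd)` per phenotype (variables as
#'   rows) plus a `creatinine` element with male/female mean and sd.
#' @export
biomarker_profiles_default <- function() {
  vars <- c("height", "bmi", "waist", "hip", "hdl", "ldl", "dbp", "sbp",
            "fpg", "tc", "tg", "uric_acid", "homa_ir", "hscrp", "hba1c")
  tab <- list(
    MHNW = c(160.86, 8.12, 21.48, 1.44, 77.76, 7.12, 91.16, 5.47, 1.58, 0.49,
             2.93, 0.91, 76.98, 9.78, 118.08, 15.30, 4.94, 0.66, 4.71, 0.91,
             1.09, 0.65, 276.75, 82.64, 2.38, 3.15, 1.81, 5.24, 5.41, 0.53),
    MHOW = c(161.25, 8.04, 25.58, 1.10, 87.30, 6.82, 98.27, 5.75, 1.46, 0.34,
             3.16, 0.84, 80.54, 10.45, 123.11, 16.81, 5.04, 0.79, 4.90, 0.91,
             1.27, 0.70, 291.26, 84.42, 2.93, 4.40, 2.21, 5.25, 5.54, 0.53),
    MHO = c(160.10, 8.92, 29.59, 1.51, 95.40, 8.25, 105.01, 6.14, 1.47, 0.34,
            3.27, 0.88, 83.17, 9.92, 127.00, 14.80, 5.13, 0.94, 5.00, 0.92,
            1.25, 0.51, 292.03, 75.75, 3.43, 2.74, 2.77, 4.40, 5.66, 0.69),
    MUNW = c(160.70, 8.50, 22.00, 1.40, 80.70, 7.43, 92.16, 6.24, 1.31, 0.39,
             3.01, 1.07, 84.06, 11.11, 130.66, 18.46, 5.91, 1.54, 5.04, 1.08,
             2.33, 1.55, 325.58, 106.51, 4.89, 11.37, 2.82, 10.08, 5.67, 0.94),
    MUOW = c(161.83, 8.57, 25.79, 1.12, 89.06, 6.72, 98.59, 5.39, 1.20, 0.33,
             3.10, 1.05, 86.21, 10.44, 133.19, 18.00, 5.92, 1.71, 5.21, 1.04,
             2.82, 2.10, 358.75, 131.02, 5.23, 7.93, 2.94, 5.66, 5.83, 0.94),
    MUO = c(161.00, 8.61, 30.18, 1.92, 98.27, 7.50, 106.07, 6.15, 1.18, 0.60,
            3.13, 1.23, 89.75, 12.11, 137.72, 20.37, 6.11, 1.67, 5.22, 1.07,
            2.96, 2.15, 362.59, 115.99, 6.26, 6.58, 3.68, 5.22, 6.05, 1.02))
  out <- lapply(tab, function(x) {
    m <- matrix(x, ncol = 2, byrow = TRUE,
                dimnames = list(vars, c("mean", "sd")))
    as.data.frame(m)
  })
  out$creatinine <- list(male = c(mean = 0.90, sd = 0.16),
                         female = c(mean = 0.74, sd = 0.13))
  out
}

#' Synthetic cohort generator configuration
#'
#' Study conditions of the emulated cohort: size, age range and age-group
#' marginals, sex ratio, the marginal mix over the six metabolic-obesity
#' phenotypes, an age effect on the log-odds of metabolic abnormality, and
#' per-phenotype biomarker profiles. Defaults mirror the reference cohort
#' (n = 6276 adults aged 30-74, 46.13% men, 38.16% metabolically unhealthy).
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @param age_range two integers within [30, 74].
#' @param sex_ratio fraction male, in (0, 1).
#' @param phenotype_mix six nonnegative weights over MHNW, MHOW, MHO, MUNW,
#'   MUOW, MUO summing to 1 (within 1e-9).
#' @param age_group_weights marginal weights over the five decade groups.
#' @param age_effect increment of the metabolic-abnormality log-odds per
#'   decade of age.
#' @param biomarker_profiles per-phenotype mean/SD table, as
#'   [biomarker_profiles_default()].
#' @param smoking_by_sex,drinking_by_sex named probabilities (male, female).
#' @param treatment_rates probability of a medication flag given the
#'   corresponding latent condition (hypertension / dyslipidemia / diabetes).
#' @param missing_rate fraction of biomarker cells blanked missing-at-random
#'   (0 disables; used to exercise the eligibility filter).
#' @return validated list of class `cvdbn_cohort_config`.
#' @export
cohort_config <- function(n = 6276, seed = 1L, age_range = c(30, 74),
                          sex_ratio = 0.4613,
                          phenotype_mix = c(MHNW = 2548, MHOW = 1135,
                                            MHO = 198, MUNW = 955,
                                            MUOW = 981, MUO = 459) / 6276,
                          age_group_weights = c(1161, 1761, 1880, 1153, 321) / 6276,
                          age_effect = 0.6,
                          biomarker_profiles = biomarker_profiles_default(),
                          smoking_by_sex = c(male = 0.60, female = 0.04),
                          drinking_by_sex = c(male = 0.62, female = 0.085),
                          treatment_rates = c(hypertension = 0.35,
                                              dyslipidemia = 0.10,
                                              diabetes = 0.50),
                          missing_rate = 0) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop_field("n", "must be a nonnegative integer")
  }
  if (length(age_range) != 2 || age_range[1] < 30 || age_range[2] > 74 ||
      age_range[1] > age_range[2]) {
    stop_field("age_range", "must lie within [30, 74]")
  }
  if (!is.numeric(sex_ratio) || sex_ratio <= 0 || sex_ratio >= 1) {
    stop_field("sex_ratio", "must lie in (0, 1)")
  }
  if (length(phenotype_mix) != 6 || any(phenotype_mix < 0) ||
      abs(sum(phenotype_mix) - 1) > 1e-9) {
    stop_field("phenotype_mix", "needs six nonnegative weights summing to 1")
  }
  names(phenotype_mix) <- PHENOTYPES
  if (any(age_group_weights < 0) || abs(sum(age_group_weights) - 1) > 1e-9) {
    stop_field("age_group_weights", "must be nonnegative and sum to 1")
  }
  if (!is.numeric(age_effect) || age_effect < 0) {
    stop_field("age_effect", "must be a nonnegative log-odds increment")
  }
  for (ph in PHENOTYPES) {
    prof <- biomarker_profiles[[ph]]
    if (is.null(prof) || any(prof$sd <= 0)) {
      stop_field("biomarker_profiles", sprintf("phenotype %s needs positive SDs", ph))
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_field("missing_rate", "must lie in [0, 1)")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_range = age_range, sex_ratio = sex_ratio,
                 phenotype_mix = phenotype_mix,
                 age_group_weights = age_group_weights,
                 age_effect = age_effect,
                 biomarker_profiles = biomarker_profiles,
                 smoking_by_sex = smoking_by_sex,
                 drinking_by_sex = drinking_by_sex,
                 treatment_rates = treatment_rates,
                 missing_rate = missing_rate),
            class = "cvdbn_cohort_config")
}

cohort_columns <- function() {
  c("id", "age", "sex", "height", "weight", "bmi", "waist", "hip", "sbp",
    "dbp", "fpg", "tc", "hdl", "ldl", "tg", "uric_acid", "insulin",
    "creatinine", "hscrp", "hba1c", "smoker", "drinker",
    "on_antihypertensive", "on_lipid_lowering", "on_diabetes_treatment",
    "gen_phenotype", "gen_metabolic_health", "gen_bmi_category")
}

# Solve the metabolic-abnormality intercept so that the age-weighted average
# of plogis(a + age_effect * (group - 3)) equals the configured MU fraction.
mu_intercept <- function(p_mu, weights, age_effect) {
  if (p_mu <= 0) return(-Inf)
  if (p_mu >= 1) return(Inf)
  f <- function(a) sum(weights * plogis(a + age_effect * (seq_along(weights) - 3))) - p_mu
  uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Generate a synthetic cohort
#'
#' Draws `n` participant records under the layered generative model: sex and
#' age group first, then metabolic health with an age-dependent logit, then
#' the BMI category given metabolic health (so the marginal phenotype
#' frequencies match `phenotype_mix` in expectation), then biomarkers from
#' the per-phenotype profiles as zero-truncated normals. Medication flags are
#' set only when the corresponding latent condition holds. Identical
#' configurations (including the seed) give identical tables.
#'
#' The `gen_*` columns record the generator's assigned labels; downstream
#' phenotyping re-derives its own labels from the biomarkers, as it would on
#' observed data.
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per participant (see `gen_*` note above;
#'   flags coded 0/1, sex coded "male"/"female").
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cvdbn_cohort_config"))
  n <- config$n
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cohort_columns())),
                                  cohort_columns()))
    out$sex <- character(0)
    out$gen_phenotype <- character(0)
    out$gen_metabolic_health <- character(0)
    out$gen_bmi_category <- character(0)
    return(out)
  }
  set.seed(config$seed)

  # layer 1: demographics
  age_group <- sample.int(5, n, replace = TRUE, prob = config$age_group_weights)
  group_lo <- c(30, 40, 50, 60, 70)
  group_hi <- c(39, 49, 59, 69, 74)
  age <- group_lo[age_group] +
    floor(runif(n) * (group_hi[age_group] - group_lo[age_group] + 1))
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")

  # layer 2: metabolic health with an age-dependent logit, then BMI category
  p_mu <- sum(config$phenotype_mix[c("MUNW", "MUOW", "MUO")])
  a0 <- mu_intercept(p_mu, config$age_group_weights, config$age_effect)
  mu <- runif(n) < plogis(a0 + config$age_effect * (age_group - 3))
  metabolic_health <- ifelse(mu, "MU", "MH")
  bmi_split_mh <- config$phenotype_mix[c("MHNW", "MHOW", "MHO")]
  bmi_split_mu <- config$phenotype_mix[c("MUNW", "MUOW", "MUO")]
  draw_cat <- function(p, u) 1L + (u > p[1]) + (u > p[1] + p[2])
  u <- runif(n)
  bmi_cat <- integer(n)
  bmi_cat[!mu] <- draw_cat(bmi_split_mh / sum(bmi_split_mh), u[!mu])
  bmi_cat[mu] <- draw_cat(bmi_split_mu / sum(bmi_split_mu), u[mu])
  bmi_category <- c("normal", "overweight", "obese")[bmi_cat]
  phenotype <- paste0(metabolic_health,
                      c("NW", "OW", "O")[bmi_cat])

  # layer 3: biomarkers from per-phenotype truncated-normal profiles
  vars <- rownames(config$biomarker_profiles$MHNW)
  mean_tab <- vapply(PHENOTYPES, function(ph)
    setNames(config$biomarker_profiles[[ph]]$mean, vars), numeric(length(vars)))
  sd_tab <- vapply(PHENOTYPES, function(ph)
    setNames(config$biomarker_profiles[[ph]]$sd, vars), numeric(length(vars)))
  prof_mean <- function(var) unname(mean_tab[var, phenotype])
  prof_sd <- function(var) unname(sd_tab[var, phenotype])
  draw <- function(var, lower = 0, upper = Inf) {
    rtruncnorm(n, prof_mean(var), prof_sd(var), lower, upper)
  }
  bmi_bounds <- rbind(normal = c(18.5, 24 - 1e-6), overweight = c(24, 28 - 1e-6),
                      obese = c(28, 45))
  bmi <- rtruncnorm(n, prof_mean("bmi"), prof_sd("bmi"),
                    bmi_bounds[bmi_cat, 1], bmi_bounds[bmi_cat, 2])
  height <- draw("height", lower = 120, upper = 200)
  weight <- bmi * (height / 100)^2
  waist <- draw("waist", lower = 40)
  hip <- draw("hip", lower = 50)
  # systolic and diastolic pressure are drawn as a correlated pair (the two
  # alternatives of the same ATP-III criterion); the conditional-normal draw
  # leaves each marginal mean/SD at its configured profile value
  rho_bp <- 0.75
  sbp <- draw("sbp", lower = 70)
  dbp_mu <- prof_mean("dbp") +
    rho_bp * prof_sd("dbp") / prof_sd("sbp") * (sbp - prof_mean("sbp"))
  dbp <- rtruncnorm(n, dbp_mu, prof_sd("dbp") * sqrt(1 - rho_bp^2), 40, Inf)
  fpg <- draw("fpg", lower = 2)
  tc <- draw("tc", lower = 1)
  hdl <- draw("hdl", lower = 0.3)
  ldl <- draw("ldl", lower = 0.3)
  tg <- draw("tg")
  uric_acid <- draw("uric_acid", lower = 50)
  homa_ir <- draw("homa_ir")
  hscrp <- draw("hscrp")
  hba1c <- draw("hba1c", lower = 3)
  insulin <- homa_ir * 22.5 / fpg  # so HOMA-IR recomputes to the drawn value
  cre <- config$biomarker_profiles$creatinine
  creatinine <- rtruncnorm(
    n, ifelse(sex == "male", cre$male["mean"], cre$female["mean"]),
    ifelse(sex == "male", cre$male["sd"], cre$female["sd"]), lower = 0.2)

  # behaviours and medication flags (flags only under the latent condition)
  smoker <- as.integer(runif(n) < config$smoking_by_sex[
    ifelse(sex == "male", "male", "female")])
  drinker <- as.integer(runif(n) < config$drinking_by_sex[
    ifelse(sex == "male", "male", "female")])
  latent_htn <- sbp >= 140 | dbp >= 90
  latent_dyslip <- tg >= 2.26 | ldl >= 4.14
  latent_dm <- fpg >= 7.0
  on_antihypertensive <- as.integer(
    latent_htn & runif(n) < config$treatment_rates["hypertension"])
  on_lipid_lowering <- as.integer(
    latent_dyslip & runif(n) < config$treatment_rates["dyslipidemia"])
  on_diabetes_treatment <- as.integer(
    latent_dm & runif(n) < config$treatment_rates["diabetes"])

  out <- data.frame(
    id = seq_len(n), age = age, sex = sex, height = height, weight = weight,
    bmi = bmi, waist = waist, hip = hip, sbp = sbp, dbp = dbp, fpg = fpg,
    tc = tc, hdl = hdl, ldl = ldl, tg = tg, uric_acid = uric_acid,
    insulin = insulin, creatinine = creatinine, hscrp = hscrp, hba1c = hba1c,
    smoker = smoker, drinker = drinker,
    on_antihypertensive = on_antihypertensive,
    on_lipid_lowering = on_lipid_lowering,
    on_diabetes_treatment = on_diabetes_treatment,
    gen_phenotype = phenotype, gen_metabolic_health = metabolic_health,
    gen_bmi_category = bmi_category, stringsAsFactors = FALSE)

  if (config$missing_rate > 0) {
    biom <- c("sbp", "dbp", "fpg", "tc", "hdl", "ldl", "tg", "uric_acid",
              "insulin", "creatinine", "hscrp", "hba1c")
    for (v in biom) {
      out[[v]][runif(n) < config$missing_rate] <- NA_real_
    }
  }
  out
}

#' Column dictionary of the synthetic cohort
#'
#' @return data frame documenting each cohort column: name, units and coding.
#' @export
cohort_dictionary <- function() {
  path <- system.file("extdata", "cohort_dictionary.csv", package = "cvdbn")
  read.csv(path, stringsAsFactors = FALSE)
}
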