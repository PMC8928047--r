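# Sex-specific 10-year general-CVD Framingham risk: coefficient config,
# risk computation, categorisation, and the study eligibility filter.

#' Framingham general-CVD coefficients
#'
#' Loads the packaged, versioned transcription of the sex-specific 10-year
#' general cardiovascular disease risk equation (lipid-based variant:
#' ln age, ln total cholesterol, ln HDL-C, ln SBP with separate treated and
#' untreated coefficients, smoking and diabetes indicators, plus each sex's
#' baseline 10-year survival S0 and mean linear predictor). The config
#' declares its expected units; cholesterol inputs in mmol/L are converted
#' before the log transform.
#'
#' @param path YAML file; defaults to the packaged transcription.
#' @return named list with `version`, `units`, `male`, `female`.
#' @export
frs_coefficients <- function(path = system.file("extdata",
                                                "frs_general_cvd_2008.yaml",
                                                package = "cvdbn")) {
  cfg <- yaml::read_yaml(path)
  for (s in c("male", "female")) {
    blk <- cfg[[s]]
    if (is.null(blk)) stop_field(s, "coefficient block missing")
    if (blk$s0 <= 0 || blk$s0 >= 1) stop_field(paste0(s, "$s0"), "must lie in (0, 1)")
  }
  if (is.null(cfg$version) || !nzchar(cfg$version)) {
    stop_field("version", "must be a nonempty string")
  }
  cfg
}

MMOL_TO_MGDL_CHOL <- 38.67

#' 10-year general-CVD Framingham risk
#'
#' Linear predictor = sum of beta * transformed covariate (the treated-SBP
#' beta is used iff `on_antihypertensive`); risk (%) =
#' `100 * (1 - S0 ^ exp(lp - mean_lp))`, clamped to [0, 100], then banded
#' low / moderate / high.
#'
#' @param profiles data frame with sex ("male"/"female"), age (30-74), tc,
#'   hdl (cholesterol), sbp (mm Hg), on_antihypertensive, smoker, diabetes
#'   (0/1 or logical).
#' @param coefficients a [frs_coefficients()] config.
#' @param units units of `tc`/`hdl` in `profiles`; "mmol/L" (default,
#'   converted at 38.67 mg/dL per mmol/L) or "mg/dL".
#' @return data frame: `linear_predictor`, `risk_percent`, `category`.
#' @export
compute_frs <- function(profiles, coefficients = frs_coefficients(),
                        units = c("mmol/L", "mg/dL")) {
  units <- match.arg(units)
  require_fields(profiles, c("sex", "age", "tc", "hdl", "sbp",
                             "on_antihypertensive", "smoker", "diabetes"),
                 "compute_frs")
  if (!all(profiles$sex %in% c("male", "female"))) {
    stop_field("sex", "must be coded male/female")
  }
  if (any(profiles$tc <= 0 | profiles$hdl <= 0 | profiles$sbp <= 0)) {
    stop_field("tc/hdl/sbp", "must be strictly positive (log transform)")
  }
  if (any(profiles$age < 30 | profiles$age > 74)) {
    stop_field("age", "must lie in [30, 74] (apply the eligibility filter first)")
  }
  tc <- profiles$tc
  hdl <- profiles$hdl
  if (units == "mmol/L" && identical(coefficients$units$cholesterol, "mg/dL")) {
    tc <- tc * MMOL_TO_MGDL_CHOL
    hdl <- hdl * MMOL_TO_MGDL_CHOL
  }
  male <- profiles$sex == "male"
  pick <- function(field) {
    ifelse(male, coefficients$male[[field]], coefficients$female[[field]])
  }
  b_sbp <- ifelse(profiles$on_antihypertensive == 1,
                  pick("ln_sbp_treated"), pick("ln_sbp_untreated"))
  lp <- pick("ln_age") * log(profiles$age) +
    pick("ln_tc") * log(tc) +
    pick("ln_hdl") * log(hdl) +
    b_sbp * log(profiles$sbp) +
    pick("smoker") * (profiles$smoker == 1) +
    pick("diabetes") * (profiles$diabetes == 1)
  risk <- 100 * (1 - pick("s0")^exp(lp - pick("mean_lp")))
  risk <- pmin(pmax(risk, 0), 100)
  data.frame(linear_predictor = lp, risk_percent = risk,
             category = categorize_frs(risk))
}

#' Band a 10-year risk percentage
#'
#' low: [0, 10); moderate: [10, 20); high: [20, 100]. The printed bands
#' ("10%-19%", ">=20%") are resolved as half-open intervals so the three
#' categories partition [0, 100] for continuous risks.
#'
#' @param risk_percent numeric vector in [0, 100].
#' @return factor with levels low/moderate/high.
#' @export
categorize_frs <- function(risk_percent) {
  if (any(risk_percent < 0 | risk_percent > 100, na.rm = TRUE)) {
    stop_field("risk_percent", "must lie in [0, 100]")
  }
  cut(risk_percent, breaks = c(0, 10, 20, Inf), right = FALSE,
      labels = c("low", "moderate", "high"), include.lowest = TRUE)
}

#' Fields a record must carry to be analysed
#' @return character vector of required column names.
#' @export
eligibility_fields <- function() {
  c("age", "sex", "bmi", "sbp", "dbp", "fpg", "tc", "hdl", "ldl", "tg",
    "uric_acid", "insulin", "creatinine", "smoker",
    "on_antihypertensive", "on_lipid_lowering", "on_diabetes_treatment")
}

#' Study eligibility filter
#'
#' Retains records aged 30-74 with BMI >= 18.5 and no missing value in any
#' field required by phenotyping or the risk score; every exclusion is
#' counted under its (first applicable) reason. Nothing is imputed or
#' silently reclassified.
#'
#' @param cohort cohort data frame.
#' @param required required fields; defaults to [eligibility_fields()].
#' @return list with `eligible` (data frame) and `exclusions` (named counts:
#'   age_below_30, age_above_74, underweight_bmi, incomplete).
#' @export
apply_eligibility <- function(cohort, required = eligibility_fields()) {
  missing_col <- setdiff(required, names(cohort))
  if (length(missing_col) > 0) {
    stop(sprintf("cohort lacks required column(s): %s",
                 paste(missing_col, collapse = ", ")), call. = FALSE)
  }
  incomplete <- rowSums(is.na(cohort[required])) > 0
  age_lo <- !is.na(cohort$age) & cohort$age < 30
  age_hi <- !is.na(cohort$age) & cohort$age > 74
  underweight <- !is.na(cohort$bmi) & cohort$bmi < 18.5
  reason <- rep(NA_character_, nrow(cohort))
  reason[incomplete] <- "incomplete"
  reason[underweight] <- "underweight_bmi"
  reason[age_hi] <- "age_above_74"
  reason[age_lo] <- "age_below_30"
  keep <- is.na(reason)
  exclusions <- c(age_below_30 = sum(reason == "age_below_30", na.rm = TRUE),
                  age_above_74 = sum(reason == "age_above_74", na.rm = TRUE),
                  underweight_bmi = sum(reason == "underweight_bmi", na.rm = TRUE),
                  incomplete = sum(reason == "incomplete", na.rm = TRUE))
  list(eligible = cohort[keep, , drop = FALSE], exclusions = exclusions)
}

#' Append Framingham risk columns to a phenotyped cohort
#'
#' @param cohort phenotyped cohort (needs the `diabetes` flag from
#'   [flag_comorbidities()]).
#' @param coefficients a [frs_coefficients()] config.
#' @return the input with `frs_percent` and `frs_category` appended.
#' @export
score_cohort <- function(cohort, coefficients = frs_coefficients()) {
  res <- compute_frs(cohort, coefficients)
  cohort$frs_percent <- res$risk_percent
  cohort$frs_category <- res$category
  cohort
}
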