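# Metabolic-obesity phenotyping: Chinese-adult BMI categories, ATP-III
# metabolic health, HOMA-IR, comorbidity flags.

#' ATP-III metabolic-health thresholds
#'
#' The four criteria defining metabolic abnormality (elevated blood pressure,
#' triglycerides or fasting glucose — each alternatively satisfied by the
#' matching medication flag — and sex-specific reduced HDL-C). Overriding a
#' default is reported with a message so nonstandard analyses are visible.
#'
#' @param ... named overrides of `sbp`, `dbp`, `tg`, `fpg`, `hdl_male`,
#'   `hdl_female`.
#' @return named list of thresholds (mm Hg / mmol/L).
#' @export
mets_thresholds <- function(...) {
  defaults <- list(sbp = 130, dbp = 85, tg = 1.7, fpg = 5.6,
                   hdl_male = 1.04, hdl_female = 1.3)
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad) > 0) stop_field("...", paste("unknown threshold(s):", paste(bad, collapse = ", ")))
  if (length(override) > 0) {
    message("metabolic-health thresholds overridden: ",
            paste(names(override), unlist(override), sep = "=", collapse = ", "))
  }
  modifyList(defaults, override)
}

#' BMI category (Chinese adult cut points)
#'
#' Half-open bins: normal weight [18.5, 24), overweight [24, 28), obese
#' [28, Inf). Underweight values must be excluded upstream (see
#' [apply_eligibility()]); they raise an error here rather than being
#' silently reclassified.
#'
#' @param bmi numeric vector, kg/m2.
#' @return factor with levels normal/overweight/obese.
#' @export
classify_bmi <- function(bmi) {
  if (anyNA(bmi)) stop_field("bmi", "contains missing values")
  if (any(bmi < 18.5)) {
    stop(sprintf("BMI below 18.5 kg/m2 (min %.2f): underweight records must be excluded before phenotyping",
                 min(bmi)), call. = FALSE)
  }
  cut(bmi, breaks = c(18.5, 24, 28, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"), include.lowest = TRUE)
}

#' Count ATP-III metabolic-abnormality criteria
#'
#' Counts, per record, how many of the four criteria hold (thresholds
#' inclusive): (1) SBP >= 130 or DBP >= 85 mm Hg or antihypertensive use;
#' (2) TG >= 1.7 mmol/L or lipid-lowering use; (3) FPG >= 5.6 mmol/L or
#' diabetes treatment; (4) HDL-C < 1.04 (men) / < 1.3 (women) mmol/L.
#'
#' @param records data frame with sbp, dbp, tg, fpg, hdl, sex and the
#'   medication flags `on_antihypertensive`, `on_lipid_lowering`,
#'   `on_diabetes_treatment`.
#' @param thresholds a [mets_thresholds()] list.
#' @return integer vector in 0..4.
#' @export
count_mets_criteria <- function(records, thresholds = mets_thresholds()) {
  require_fields(records, c("sbp", "dbp", "tg", "fpg", "hdl", "sex",
                            "on_antihypertensive", "on_lipid_lowering",
                            "on_diabetes_treatment"),
                 "count_mets_criteria")
  hdl_cut <- ifelse(records$sex == "male", thresholds$hdl_male,
                    thresholds$hdl_female)
  c1 <- records$sbp >= thresholds$sbp | records$dbp >= thresholds$dbp |
    records$on_antihypertensive == 1
  c2 <- records$tg >= thresholds$tg | records$on_lipid_lowering == 1
  c3 <- records$fpg >= thresholds$fpg | records$on_diabetes_treatment == 1
  c4 <- records$hdl < hdl_cut
  as.integer(c1) + as.integer(c2) + as.integer(c3) + as.integer(c4)
}

#' Metabolic health status from a criteria count
#'
#' Metabolically unhealthy (MU) iff at least two of the four criteria hold.
#'
#' @param criteria_count integer vector in 0..4.
#' @return factor with levels MH/MU.
#' @export
classify_metabolic_health <- function(criteria_count) {
  if (any(criteria_count < 0 | criteria_count > 4 |
          criteria_count != round(criteria_count))) {
    stop_field("criteria_count", "must be integers in 0..4")
  }
  factor(ifelse(criteria_count >= 2, "MU", "MH"), levels = c("MH", "MU"))
}

#' Metabolic-obesity phenotype
#'
#' The unique cell of the 2 x 3 cross of metabolic health and BMI category:
#' MHNW, MHOW, MHO, MUNW, MUOW, MUO.
#'
#' @param metabolic_health factor/character, MH or MU.
#' @param bmi_category factor/character, normal/overweight/obese.
#' @return factor over the six phenotypes.
#' @export
assign_phenotype <- function(metabolic_health, bmi_category) {
  mh <- as.character(metabolic_health)
  bc <- as.character(bmi_category)
  if (!all(mh %in% c("MH", "MU"))) stop_field("metabolic_health", "must be MH or MU")
  if (!all(bc %in% c("normal", "overweight", "obese"))) {
    stop_field("bmi_category", "must be normal/overweight/obese")
  }
  suffix <- c(normal = "NW", overweight = "OW", obese = "O")
  factor(paste0(mh, suffix[bc]), levels = PHENOTYPES)
}

#' Homeostasis model of insulin resistance
#'
#' `HOMA-IR = fasting insulin (uIU/mL) x FPG (mmol/L) / 22.5`.
#'
#' @param insulin fasting insulin, uIU/mL, nonnegative.
#' @param fpg fasting plasma glucose, mmol/L, nonnegative.
#' @return dimensionless HOMA-IR.
#' @export
compute_homa_ir <- function(insulin, fpg) {
  if (any(insulin < 0, na.rm = TRUE)) stop_field("insulin", "must be nonnegative")
  if (any(fpg < 0, na.rm = TRUE)) stop_field("fpg", "must be nonnegative")
  insulin * fpg / 22.5
}

#' Comorbidity flags
#'
#' Hypertension: SBP >= 140 or DBP >= 90 mm Hg or antihypertensive use.
#' Diabetes: FPG >= 7.0 mmol/L or diabetes treatment. Dyslipidemia (default
#' `any` connective): LDL-C >= 4.14, HDL-C <= 1.036 or TG >= 2.26 mmol/L, or
#' lipid-lowering use; `all` requires the three lipid criteria jointly.
#' Hyperuricemia: serum uric acid >= 420 umol/L (men) / >= 360 umol/L
#' (women).
#'
#' @param records data frame with the required biomarker and flag columns.
#' @param dyslipidemia_rule connective for the three lipid criteria.
#' @return data frame of logicals: hypertension, diabetes, dyslipidemia,
#'   hyperuricemia.
#' @export
flag_comorbidities <- function(records, dyslipidemia_rule = c("any", "all")) {
  dyslipidemia_rule <- match.arg(dyslipidemia_rule)
  require_fields(records, c("sbp", "dbp", "fpg", "ldl", "hdl", "tg",
                            "uric_acid", "sex", "on_antihypertensive",
                            "on_lipid_lowering", "on_diabetes_treatment"),
                 "flag_comorbidities")
  lip <- cbind(records$ldl >= 4.14, records$hdl <= 1.036, records$tg >= 2.26)
  dys <- if (dyslipidemia_rule == "any") rowSums(lip) > 0 else rowSums(lip) == 3
  data.frame(
    hypertension = records$sbp >= 140 | records$dbp >= 90 |
      records$on_antihypertensive == 1,
    diabetes = records$fpg >= 7.0 | records$on_diabetes_treatment == 1,
    dyslipidemia = dys | records$on_lipid_lowering == 1,
    hyperuricemia = ifelse(records$sex == "male", records$uric_acid >= 420,
                           records$uric_acid >= 360))
}

#' Derive all phenotyping columns for a cohort
#'
#' Augments an eligible cohort table with the BMI category, criteria count,
#' metabolic health, six-level phenotype, comorbidity flags, HOMA-IR and
#' CKD-EPI eGFR.
#'
#' @param cohort eligible cohort data frame (see [apply_eligibility()]).
#' @param thresholds a [mets_thresholds()] list.
#' @param egfr_coefficients a [ckd_epi_coefficients()] config.
#' @return the input with derived columns appended.
#' @export
phenotype_cohort <- function(cohort, thresholds = mets_thresholds(),
                             egfr_coefficients = ckd_epi_coefficients()) {
  cohort$bmi_category <- classify_bmi(cohort$bmi)
  cohort$criteria_count <- count_mets_criteria(cohort, thresholds)
  cohort$metabolic_health <- classify_metabolic_health(cohort$criteria_count)
  cohort$phenotype <- assign_phenotype(cohort$metabolic_health,
                                       cohort$bmi_category)
  flags <- flag_comorbidities(cohort)
  cohort[names(flags)] <- flags
  cohort$homa_ir <- compute_homa_ir(cohort$insulin, cohort$fpg)
  cohort$egfr <- compute_egfr(cohort$creatinine, cohort$age, cohort$sex,
                              egfr_coefficients)
  cohort
}
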