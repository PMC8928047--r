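#' CKD-EPI 2009 creatinine equation coefficients
#'
#' Loads the packaged, versioned transcription of the CKD-EPI serum
#' creatinine equation (2009): per-sex kappa and alpha, the shared scale,
#' the exponent above kappa and the age base. The race multiplier is not
#' applied (all-Chinese cohort). Coefficients live in an editable YAML file
#' so an alternative eGFR equation can be swapped in.
#'
#' @param path YAML file; defaults to the packaged transcription.
#' @return named list with `version`, `male`, `female`, `common`.
#' @export
ckd_epi_coefficients <- function(path = system.file("extdata", "ckd_epi_2009.yaml",
                                                    package = "cvdbn")) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$version), !is.null(cfg$male), !is.null(cfg$female))
  cfg
}

#' Estimated glomerular filtration rate (CKD-EPI creatinine)
#'
#' `eGFR = scale * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^exp_above *
#' age_base^age * sex_multiplier`, in mL/min/1.73 m2. Strictly decreasing in
#' creatinine and in age.
#'
#' @param creatinine serum creatinine, mg/dL, strictly positive.
#' @param age years.
#' @param sex "male"/"female".
#' @param coefficients a [ckd_epi_coefficients()] config.
#' @return eGFR vector, mL/min/1.73 m2.
#' @export
compute_egfr <- function(creatinine, age, sex,
                         coefficients = ckd_epi_coefficients()) {
  if (any(creatinine <= 0, na.rm = TRUE)) {
    stop_field("creatinine", "must be strictly positive")
  }
  if (!all(sex %in% c("male", "female"))) {
    stop_field("sex", "must be coded male/female")
  }
  kappa <- ifelse(sex == "male", coefficients$male$kappa,
                  coefficients$female$kappa)
  alpha <- ifelse(sex == "male", coefficients$male$alpha,
                  coefficients$female$alpha)
  mult <- ifelse(sex == "male", coefficients$male$sex_multiplier,
                 coefficients$female$sex_multiplier)
  com <- coefficients$common
  ratio <- creatinine / kappa
  com$scale * pmin(ratio, 1)^alpha * pmax(ratio, 1)^com$exp_above *
    com$age_base^age * mult
}
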