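test_that("BMI categories use half-open Chinese-adult bins", {
  expect_equal(as.character(classify_bmi(c(18.5, 22, 23.9, 24, 27.9, 28, 35))),
               c("normal", "normal", "normal", "overweight", "overweight",
                 "obese", "obese"))
  expect_error(classify_bmi(18.4), "underweight")
})

test_that("criteria counting matches the printed examples", {
  # borderline SBP alone
  expect_equal(count_mets_criteria(base_record(sbp = 130)), 1L)
  # TG and FPG exactly at threshold
  expect_equal(count_mets_criteria(base_record(sex = "female", tg = 1.7,
                                               fpg = 5.6)), 2L)
  # low female HDL plus antihypertensive use
  expect_equal(count_mets_criteria(base_record(sex = "female", hdl = 1.25,
                                               on_antihypertensive = 1)), 2L)
  expect_equal(count_mets_criteria(base_record()), 0L)
  # sex-specific HDL cut: 1.25 is low for women, not for men
  expect_equal(count_mets_criteria(base_record(sex = "male", hdl = 1.25)), 0L)
})

test_that("metabolic health flips at two criteria and phenotypes are a bijection", {
  expect_equal(as.character(classify_metabolic_health(c(0, 1, 2, 3, 4))),
               c("MH", "MH", "MU", "MU", "MU"))
  expect_error(classify_metabolic_health(5), "0..4")
  combos <- expand.grid(mh = c("MH", "MU"),
                        bc = c("normal", "overweight", "obese"))
  labels <- assign_phenotype(combos$mh, combos$bc)
  expect_equal(sort(as.character(labels)),
               sort(c("MHNW", "MHOW", "MHO", "MUNW", "MUOW", "MUO")))
  expect_equal(length(unique(labels)), 6)
})

test_that("HOMA-IR is insulin * FPG / 22.5", {
  expect_equal(compute_homa_ir(22.5, 1), 1)
  expect_equal(compute_homa_ir(0, 9), 0)
  expect_equal(compute_homa_ir(10, 4.5), 2)
  expect_error(compute_homa_ir(-1, 5), "nonnegative")
})

test_that("comorbidity flags follow the diagnostic thresholds", {
  f <- flag_comorbidities(base_record(sbp = 140))
  expect_true(f$hypertension)
  expect_true(flag_comorbidities(base_record(fpg = 7.0))$diabetes)
  expect_false(flag_comorbidities(base_record(fpg = 6.9))$diabetes)
  expect_true(flag_comorbidities(base_record(uric_acid = 420))$hyperuricemia)
  expect_false(flag_comorbidities(base_record(uric_acid = 419))$hyperuricemia)
  expect_true(flag_comorbidities(base_record(sex = "female",
                                             uric_acid = 360))$hyperuricemia)
  # dyslipidemia: any-of by default, all-of under the strict connective
  expect_true(flag_comorbidities(base_record(tg = 2.26))$dyslipidemia)
  expect_false(flag_comorbidities(base_record(tg = 2.26),
                                  dyslipidemia_rule = "all")$dyslipidemia)
  expect_true(flag_comorbidities(base_record(tg = 2.26, ldl = 4.14, hdl = 1.036),
                                 dyslipidemia_rule = "all")$dyslipidemia)
})

test_that("boundary behaviour matches the independent rule evaluator", {
  eps <- 1e-6
  grid <- expand.grid(
    sbp = 130 + c(-eps, 0, eps), tg = 1.7 + c(-eps, 0, eps),
    fpg = 5.6 + c(-eps, 0, eps), hdl = c(1.04 + c(-eps, 0, eps), 1.3),
    sex = c("male", "female"), on_antihypertensive = 0:1,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    rec <- base_record(sbp = grid$sbp[i], tg = grid$tg[i], fpg = grid$fpg[i],
                       hdl = grid$hdl[i], sex = grid$sex[i],
                       on_antihypertensive = grid$on_antihypertensive[i])
    expect_equal(count_mets_criteria(rec), oracle_mets_count(rec),
                 info = paste("row", i))
  }
})

test_that("medication flags can only increase the criteria count and comorbidity flags", {
  set.seed(31)
  for (i in 1:50) {
    rec <- base_record(sbp = runif(1, 100, 160), dbp = runif(1, 60, 100),
                       tg = runif(1, 0.5, 3), fpg = runif(1, 4, 8),
                       hdl = runif(1, 0.8, 2), ldl = runif(1, 2, 5),
                       uric_acid = runif(1, 200, 500),
                       sex = sample(c("male", "female"), 1))
    base_count <- count_mets_criteria(rec)
    base_flags <- unlist(flag_comorbidities(rec))
    for (med in c("on_antihypertensive", "on_lipid_lowering",
                  "on_diabetes_treatment")) {
      up <- rec
      up[[med]] <- 1
      expect_gte(count_mets_criteria(up), base_count)
      expect_true(all(unlist(flag_comorbidities(up)) >= base_flags))
    }
  }
})

test_that("missing required fields are reported by name", {
  rec <- base_record()
  rec$hdl <- NA_real_
  expect_error(count_mets_criteria(rec), "hdl")
  rec2 <- base_record()
  rec2$uric_acid <- NULL
  expect_error(flag_comorbidities(rec2), "uric_acid")
})

test_that("every complete record maps to exactly one phenotype", {
  cohort <- generate_cohort(cohort_config(n = 2000, seed = 8))
  ph <- phenotype_cohort(cohort)
  expect_false(anyNA(ph$phenotype))
  expect_true(all(ph$phenotype %in% c("MHNW", "MHOW", "MHO", "MUNW", "MUOW",
                                      "MUO")))
  expect_identical(as.character(ph$phenotype),
                   as.character(assign_phenotype(ph$metabolic_health,
                                                 ph$bmi_category)))
})
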