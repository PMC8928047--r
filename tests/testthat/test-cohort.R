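test_that("configuration invariants are enforced with the field named", {
  expect_error(cohort_config(n = -1), "'n'")
  expect_error(cohort_config(age_range = c(25, 74)), "age_range")
  expect_error(cohort_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(cohort_config(phenotype_mix = rep(0.2, 6)), "phenotype_mix")
  prof <- biomarker_profiles_default()
  prof$MUO$sd[1] <- 0
  expect_error(cohort_config(biomarker_profiles = prof), "biomarker_profiles")
})

test_that("n = 0 yields an empty table with the full column set", {
  empty <- generate_cohort(cohort_config(n = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("age", "sex", "bmi", "tg", "gen_phenotype") %in%
                    names(empty)))
})

test_that("identical configurations give identical cohorts", {
  c1 <- generate_cohort(cohort_config(n = 500, seed = 12))
  c2 <- generate_cohort(cohort_config(n = 500, seed = 12))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(n = 500, seed = 13))
  expect_false(identical(c1, c3))
})

test_that("phenotype frequencies match the configured mix", {
  n <- 20000
  cohort <- generate_cohort(cohort_config(n = n, seed = 14))
  mix <- cohort_config()$phenotype_mix
  freq <- table(factor(cohort$gen_phenotype, levels = names(mix))) / n
  for (ph in names(mix)) {
    tol <- 3 * sqrt(mix[[ph]] * (1 - mix[[ph]]) / n)
    expect_lt(abs(freq[[ph]] - mix[[ph]]), tol)
  }
})

test_that("biomarker means track the configured truncated-normal targets", {
  n <- 50000
  cohort <- generate_cohort(cohort_config(n = n, seed = 15))
  prof <- biomarker_profiles_default()
  # TG: the configured MUO and MHNW distributions (mean of a normal with the
  # profile mu/sigma truncated at zero) are the analytic targets
  target <- function(ph) {
    cvdbn:::etruncnorm(prof[[ph]]["tg", "mean"], prof[[ph]]["tg", "sd"], 0)
  }
  for (ph in c("MHNW", "MUO")) {
    x <- cohort$tg[cohort$gen_phenotype == ph]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - target(ph)), 3 * se)
  }
  x_muo <- cohort$tg[cohort$gen_phenotype == "MUO"]
  x_mhnw <- cohort$tg[cohort$gen_phenotype == "MHNW"]
  expect_gt(mean(x_muo), mean(x_mhnw))
  # and the MUO-MHNW gap is consistent with the configured profiles
  gap <- target("MUO") - target("MHNW")
  se_gap <- sqrt(sd(x_muo)^2 / length(x_muo) + sd(x_mhnw)^2 / length(x_mhnw))
  expect_lt(abs((mean(x_muo) - mean(x_mhnw)) - gap), 3 * se_gap)
})

test_that("medication flags appear only under their latent condition", {
  cohort <- generate_cohort(cohort_config(n = 20000, seed = 16))
  expect_true(all(cohort$sbp >= 140 | cohort$dbp >= 90 |
                    cohort$on_antihypertensive == 0))
  expect_true(all(cohort$tg >= 2.26 | cohort$ldl >= 4.14 |
                    cohort$on_lipid_lowering == 0))
  expect_true(all(cohort$fpg >= 7 | cohort$on_diabetes_treatment == 0))
  # and they do occur
  expect_gt(sum(cohort$on_antihypertensive), 0)
  expect_gt(sum(cohort$on_diabetes_treatment), 0)
})

test_that("records are internally consistent", {
  cohort <- generate_cohort(cohort_config(n = 5000, seed = 17))
  expect_true(all(abs(cohort$bmi - cohort$weight / (cohort$height / 100)^2) <
                    0.1))
  bounds <- list(normal = c(18.5, 24), overweight = c(24, 28),
                 obese = c(28, Inf))
  for (bc in names(bounds)) {
    x <- cohort$bmi[cohort$gen_bmi_category == bc]
    expect_true(all(x >= bounds[[bc]][1] & x < bounds[[bc]][2]))
  }
  expect_true(all(cohort$age >= 30 & cohort$age <= 74))
  biom <- c("sbp", "dbp", "fpg", "tc", "hdl", "ldl", "tg", "uric_acid",
            "insulin", "creatinine", "hscrp", "hba1c")
  expect_true(all(as.matrix(cohort[biom]) > 0))
  # HOMA-IR reconstructs from the generated insulin and glucose
  expect_equal(compute_homa_ir(cohort$insulin, cohort$fpg),
               cohort$insulin * cohort$fpg / 22.5)
})

test_that("missing-at-random injection feeds the eligibility filter", {
  cohort <- generate_cohort(cohort_config(n = 4000, seed = 18,
                                          missing_rate = 0.02))
  expect_gt(sum(is.na(cohort$tc)), 0)
  res <- apply_eligibility(cohort)
  expect_equal(nrow(res$eligible) + sum(res$exclusions), nrow(cohort))
  expect_gt(res$exclusions[["incomplete"]], 0)
  expect_false(anyNA(res$eligible[eligibility_fields()]))
})

test_that("the metabolic-abnormality rate rises with age as configured", {
  cohort <- generate_cohort(cohort_config(n = 50000, seed = 19))
  rate <- tapply(cohort$gen_metabolic_health == "MU",
                 cut(cohort$age, c(30, 40, 50, 60, 70, Inf), right = FALSE),
                 mean)
  expect_true(all(diff(rate) > 0))
  # overall MU fraction matches the phenotype mix
  p_mu <- sum(cohort_config()$phenotype_mix[c("MUNW", "MUOW", "MUO")])
  expect_lt(abs(mean(cohort$gen_metabolic_health == "MU") - p_mu),
            3 * sqrt(p_mu * (1 - p_mu) / 50000))
})
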