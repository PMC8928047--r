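test_that("risk at the sex mean linear predictor equals 100 * (1 - S0)", {
  coeffs <- frs_coefficients()
  for (s in c("male", "female")) {
    blk <- coeffs[[s]]
    # build a profile whose linear predictor hits the sex's published mean by
    # solving for SBP with the remaining covariates fixed
    age <- 55; tc <- 5.2 * 38.67; hdl <- 1.3 * 38.67
    rest <- blk$ln_age * log(age) + blk$ln_tc * log(tc) + blk$ln_hdl * log(hdl)
    sbp <- exp((blk$mean_lp - rest) / blk$ln_sbp_untreated)
    res <- compute_frs(data.frame(sex = s, age = age, tc = 5.2, hdl = 1.3,
                                  sbp = sbp, on_antihypertensive = 0,
                                  smoker = 0, diabetes = 0))
    expect_equal(res$risk_percent, 100 * (1 - blk$s0), tolerance = 1e-9)
  }
})

test_that("risk is monotone in each covariate with the published signs", {
  base <- function(...) base_record(age = 55, tc = 5.2, hdl = 1.2, sbp = 130,
                                    diabetes = 0, ...)
  risk <- function(rec) compute_frs(rec)$risk_percent
  expect_true(all(diff(sapply(c(40, 50, 60, 70),
                              function(a) risk(base(age = a)))) > 0))
  expect_true(all(diff(sapply(c(4, 5, 6, 7),
                              function(t) risk(base(tc = t)))) > 0))
  expect_true(all(diff(sapply(c(110, 130, 150, 170),
                              function(s) risk(base(sbp = s)))) > 0))
  expect_true(all(diff(sapply(c(0.9, 1.2, 1.5, 1.8),
                              function(h) risk(base(hdl = h)))) < 0))
  expect_gt(risk(base(smoker = 1)), risk(base()))
  expect_gt(risk(base(diabetes = 1)), risk(base()))
})

test_that("a fixed profile matches the independent transcription", {
  res <- compute_frs(data.frame(sex = "male", age = 55, tc = 5.2, hdl = 1.2,
                                sbp = 130, on_antihypertensive = 0,
                                smoker = 1, diabetes = 0))
  expect_equal(res$risk_percent,
               oracle_frs("male", 55, 5.2, 1.2, 130, FALSE, TRUE, FALSE),
               tolerance = 1e-8)
})

test_that("1000 random eligible profiles match the oracle to 1e-8", {
  set.seed(77)
  n <- 1000
  prof <- data.frame(
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 30, 74),
    tc = runif(n, 2.5, 8), hdl = runif(n, 0.6, 2.5),
    sbp = runif(n, 90, 200),
    on_antihypertensive = rbinom(n, 1, 0.3),
    smoker = rbinom(n, 1, 0.3), diabetes = rbinom(n, 1, 0.1))
  ours <- compute_frs(prof)
  theirs <- vapply(seq_len(n), function(i) {
    oracle_frs(prof$sex[i], prof$age[i], prof$tc[i], prof$hdl[i], prof$sbp[i],
               prof$on_antihypertensive[i] == 1, prof$smoker[i] == 1,
               prof$diabetes[i] == 1)
  }, numeric(1))
  expect_equal(ours$risk_percent, theirs, tolerance = 1e-8)
  # categories agree with direct thresholding, exactly
  expect_identical(as.character(ours$category),
                   as.character(cut(ours$risk_percent, c(0, 10, 20, Inf),
                                    right = FALSE, include.lowest = TRUE,
                                    labels = c("low", "moderate", "high"))))
})

test_that("risk bands partition [0, 100] with half-open boundaries", {
  expect_equal(as.character(categorize_frs(c(0, 9.99, 10, 15, 19.5, 20, 100))),
               c("low", "low", "moderate", "moderate", "moderate", "high",
                 "high"))
  expect_error(categorize_frs(-1), "0, 100")
  expect_error(categorize_frs(101), "0, 100")
})

test_that("swapping the sex coefficient blocks changes every nontrivial result", {
  cfg <- frs_coefficients()
  swapped <- cfg
  swapped$male <- cfg$female
  swapped$female <- cfg$male
  prof <- data.frame(sex = c("male", "female"), age = 60, tc = 5.5, hdl = 1.1,
                     sbp = 140, on_antihypertensive = 0, smoker = 1,
                     diabetes = 0)
  r1 <- compute_frs(prof, cfg)$risk_percent
  r2 <- compute_frs(prof, swapped)$risk_percent
  expect_true(all(abs(r1 - r2) > 1e-6))
})

test_that("eligibility retains 30-74 year olds with complete non-underweight records", {
  cohort <- do.call(rbind, lapply(c(29, 30, 74, 75), function(a)
    base_record(age = a)))
  res <- apply_eligibility(cohort)
  expect_equal(res$eligible$age, c(30, 74))
  expect_equal(res$exclusions[["age_below_30"]], 1)
  expect_equal(res$exclusions[["age_above_74"]], 1)

  miss <- base_record()
  miss$hdl <- NA_real_
  res2 <- apply_eligibility(rbind(base_record(), miss))
  expect_equal(nrow(res2$eligible), 1)
  expect_equal(res2$exclusions[["incomplete"]], 1)

  thin <- base_record(bmi = 17.9)
  expect_equal(apply_eligibility(rbind(base_record(), thin))$exclusions[["underweight_bmi"]], 1)

  clean <- do.call(rbind, lapply(1:5, function(i) base_record(age = 30 + i)))
  res3 <- apply_eligibility(clean)
  expect_identical(res3$eligible, clean)
  expect_true(all(res3$exclusions == 0))
})

test_that("invalid risk inputs raise range errors", {
  expect_error(compute_frs(base_record(tc = 0, diabetes = 0)), "positive")
  expect_error(compute_frs(base_record(age = 29, diabetes = 0)), "age")
  rec <- base_record(diabetes = 0)
  rec$sex <- "other"
  expect_error(compute_frs(rec), "male/female")
})
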