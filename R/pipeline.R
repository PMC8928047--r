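# End-to-end orchestration: cohort -> eligibility -> phenotyping -> risk
# scoring -> discretization -> bootstrap structure learning -> averaging ->
# CPT fitting -> conditional-probability reasoning -> descriptive reports.

#' Default reasoning scenarios
#'
#' The evidence sweeps reported by the analysis: the five age groups, the
#' six metabolic-obesity phenotypes (metabolic health x BMI category), and
#' the phenotypes split by sex.
#'
#' @return named list of evidence lists.
#' @export
default_scenarios <- function() {
  sc <- list()
  for (g in AGE_GROUP_LEVELS) {
    sc[[paste0("age:", g)]] <- list(age_group = g)
  }
  combos <- expand.grid(mh = c("MH", "MU"),
                        bmi = c("normal", "overweight", "obese"),
                        stringsAsFactors = FALSE)
  label <- function(mh, bmi) paste0(mh, c(normal = "NW", overweight = "OW",
                                          obese = "O")[bmi])
  for (i in seq_len(nrow(combos))) {
    nm <- label(combos$mh[i], combos$bmi[i])
    sc[[nm]] <- list(metabolic_health = combos$mh[i],
                     bmi_category = combos$bmi[i])
  }
  for (i in seq_len(nrow(combos))) {
    for (s in c("male", "female")) {
      nm <- paste0(label(combos$mh[i], combos$bmi[i]), ":", s)
      sc[[nm]] <- list(metabolic_health = combos$mh[i],
                       bmi_category = combos$bmi[i], sex = s)
    }
  }
  sc
}

#' Pipeline configuration
#'
#' Bundles every choice the end-to-end analysis depends on. Defaults encode
#' the reference study conditions: a synthetic cohort of 6276, 300 bootstrap
#' replicates, consensus thresholds 0.5 (averaged) and 0.85 strict (final),
#' the layered constraint set, and the age/phenotype/sex reasoning sweeps.
#'
#' @param generator a [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort optional externally supplied cohort data frame.
#' @param nodes network node set.
#' @param discretization map as [default_discretization()].
#' @param layers layer ordering compiled into the blacklist.
#' @param whitelist,blacklist explicit arc constraints (on top of layers).
#' @param B bootstrap replicate count.
#' @param thresholds named vector: `averaged` (kept if strength >= value)
#'   and `final` (kept if strength > value).
#' @param tabu a [tabu_params()].
#' @param scenarios reasoning scenarios, as [default_scenarios()].
#' @param replicates,n_samples Monte Carlo settings for the reasoning report.
#' @param smoothing CPT pseudo-count for [fit_cpts()].
#' @param seed global seed; every stage derives its own sub-seed from it.
#' @param out_dir optional directory to write artifacts into.
#' @return list of class `cvdbn_pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(), cohort = NULL,
                            nodes = default_bn_nodes(),
                            discretization = default_discretization(),
                            layers = default_layers(),
                            whitelist = default_whitelist(),
                            blacklist = default_blacklist(),
                            B = 300,
                            thresholds = c(averaged = 0.5, final = 0.85),
                            tabu = tabu_params(),
                            scenarios = default_scenarios(),
                            replicates = 30, n_samples = 10000,
                            smoothing = 0, seed = 1L, out_dir = NULL) {
  if (any(thresholds < 0 | thresholds > 1)) {
    stop_field("thresholds", "must lie in [0, 1]")
  }
  if (!all(c("averaged", "final") %in% names(thresholds))) {
    stop_field("thresholds", "needs named entries 'averaged' and 'final'")
  }
  for (m in names(discretization)) {
    br <- discretization[[m]]$breaks
    if (any(diff(br) <= 0)) {
      stop_field("discretization", sprintf("bin edges of '%s' must be strictly increasing", m))
    }
  }
  structure(list(generator = generator, cohort = cohort, nodes = nodes,
                 discretization = discretization, layers = layers,
                 whitelist = whitelist, blacklist = blacklist, B = B,
                 thresholds = thresholds, tabu = tabu, scenarios = scenarios,
                 replicates = replicates, n_samples = n_samples,
                 smoothing = smoothing, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "cvdbn_pipeline_config")
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes eligibility filtering, phenotyping, Framingham scoring,
#' discretization, bootstrap structure learning, arc-strength averaging at
#' both thresholds, CPT fitting on the final network, the constraint audit,
#' the conditional-probability reasoning report, and descriptive phenotype
#' tables. Fully reproducible from `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest`, `cohort` (derived columns appended),
#'   `exclusions`, `dataset`, `strengths`, `net_averaged` (threshold
#'   `averaged`, inclusive), `net_final` (threshold `final`, strict), `fit`,
#'   `audit_averaged`, `audit_final`, `report`, `table_phenotype`,
#'   `table_frs`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cvdbn_pipeline_config"))
  seed <- config$seed
  raw <- stage_fail("cohort", {
    if (!is.null(config$cohort)) config$cohort else {
      gen <- config$generator
      gen$seed <- derive_seed(seed, 11)
      generate_cohort(gen)
    }
  })
  elig <- stage_fail("eligibility", apply_eligibility(raw))
  cohort <- stage_fail("phenotyping", phenotype_cohort(elig$eligible))
  cohort <- stage_fail("framingham", score_cohort(cohort))
  dataset <- stage_fail("discretize",
                        discretize_cohort(cohort, config$discretization,
                                          config$nodes))
  constraints <- stage_fail("constraints",
                            arc_constraints(config$nodes, config$whitelist,
                                            config$blacklist, config$layers))
  dags <- stage_fail("bootstrap_learn",
                     bootstrap_learn(dataset, config$B, constraints,
                                     config$tabu, seed = derive_seed(seed, 12)))
  strengths <- stage_fail("arc_strengths", arc_strengths(dags))
  net_averaged <- stage_fail("averaged_network",
                             averaged_network(strengths,
                                              config$thresholds["averaged"]))
  net_final <- stage_fail("final_network",
                          averaged_network(strengths,
                                           config$thresholds["final"],
                                           strict = TRUE))
  fit <- stage_fail("fit_cpts",
                    suppressWarnings(fit_cpts(net_final, dataset,
                                              config$smoothing)))
  audit_averaged <- audit_constraints(net_averaged, constraints)
  audit_final <- audit_constraints(net_final, constraints)
  report <- stage_fail("reasoning", reasoning_report(
    fit, config$scenarios, outcome = "frs_category",
    replicates = config$replicates, n_samples = config$n_samples,
    seed = derive_seed(seed, 13)))
  table_phenotype <- phenotype_table(cohort)
  table_frs <- frs_table(cohort)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cvdbn")),
    config_hash = content_hash(config[setdiff(names(config), "out_dir")]),
    seed = seed,
    sub_seeds = list(cohort = derive_seed(seed, 11),
                     bootstrap = derive_seed(seed, 12),
                     reasoning = derive_seed(seed, 13)),
    counts = list(input = nrow(raw),
                  excluded = sum(elig$exclusions),
                  eligible = nrow(cohort),
                  analysed = nrow(dataset$data)),
    exclusions = as.list(elig$exclusions),
    B = config$B,
    thresholds = as.list(config$thresholds),
    timestamp = format(Sys.time(), tz = "UTC"))

  result <- list(manifest = manifest, cohort = cohort,
                 exclusions = elig$exclusions, dataset = dataset,
                 strengths = strengths, net_averaged = net_averaged,
                 net_final = net_final, fit = fit,
                 audit_averaged = audit_averaged, audit_final = audit_final,
                 report = report, table_phenotype = table_phenotype,
                 table_frs = table_frs)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

#' Descriptive phenotype table
#'
#' Group size plus mean and SD of the key continuous biomarkers for each of
#' the six derived metabolic-obesity phenotypes.
#'
#' @param cohort phenotyped (and optionally scored) cohort data frame.
#' @return data frame, one row per phenotype.
#' @export
phenotype_table <- function(cohort) {
  vars <- c("age", "bmi", "sbp", "dbp", "fpg", "tc", "hdl", "ldl", "tg",
            "uric_acid", "homa_ir", "hscrp", "egfr", "frs_percent")
  vars <- intersect(vars, names(cohort))
  out <- data.frame(phenotype = base::levels(cohort$phenotype),
                    n = as.integer(table(cohort$phenotype)))
  for (v in vars) {
    out[[paste0(v, "_mean")]] <- as.numeric(tapply(cohort[[v]], cohort$phenotype, mean))
    out[[paste0(v, "_sd")]] <- as.numeric(tapply(cohort[[v]], cohort$phenotype, stats::sd))
  }
  out
}

#' Risk-band distribution by phenotype
#'
#' Counts and percentages of the low/moderate/high 10-year risk bands within
#' each derived metabolic-obesity phenotype.
#'
#' @param cohort phenotyped and scored cohort data frame.
#' @return data frame, one row per phenotype.
#' @export
frs_table <- function(cohort) {
  tab <- table(cohort$phenotype, cohort$frs_category)
  pct <- prop.table(tab, 1) * 100
  out <- data.frame(phenotype = rownames(tab),
                    n = as.integer(rowSums(tab)))
  for (k in colnames(tab)) {
    out[[paste0(k, "_n")]] <- as.integer(tab[, k])
    out[[paste0(k, "_pct")]] <- round(as.numeric(pct[, k]), 2)
  }
  out
}
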