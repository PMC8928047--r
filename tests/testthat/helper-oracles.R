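# Independent oracles: deliberately plain, rule-by-rule reimplementations
# used to cross-check the package. They share no code with the package
# internals.

# -- phenotyping ------------------------------------------------------------

oracle_bmi_class <- function(bmi) {
  if (bmi < 18.5) stop("underweight")
  if (bmi < 24) return("normal")
  if (bmi < 28) return("overweight")
  "obese"
}

oracle_mets_count <- function(row) {
  count <- 0
  if (row$sbp >= 130) count <- count + 1
  else if (row$dbp >= 85) count <- count + 1
  else if (row$on_antihypertensive == 1) count <- count + 1
  if (row$tg >= 1.7 || row$on_lipid_lowering == 1) count <- count + 1
  if (row$fpg >= 5.6 || row$on_diabetes_treatment == 1) count <- count + 1
  if (row$sex == "male") {
    if (row$hdl < 1.04) count <- count + 1
  } else {
    if (row$hdl < 1.3) count <- count + 1
  }
  count
}

oracle_comorbidities <- function(row) {
  list(
    hypertension = row$sbp >= 140 || row$dbp >= 90 ||
      row$on_antihypertensive == 1,
    diabetes = row$fpg >= 7.0 || row$on_diabetes_treatment == 1,
    dyslipidemia = row$ldl >= 4.14 || row$hdl <= 1.036 || row$tg >= 2.26 ||
      row$on_lipid_lowering == 1,
    hyperuricemia = if (row$sex == "male") row$uric_acid >= 420 else
      row$uric_acid >= 360)
}

# -- CKD-EPI 2009, second transcription -------------------------------------

oracle_egfr <- function(creatinine, age, sex) {
  if (sex == "female") {
    kappa <- 0.7; alpha <- -0.329; mult <- 1.018
  } else {
    kappa <- 0.9; alpha <- -0.411; mult <- 1.0
  }
  141 * min(creatinine / kappa, 1)^alpha * max(creatinine / kappa, 1)^(-1.209) *
    0.993^age * mult
}

# -- Framingham general-CVD 10-year risk, second transcription --------------
# Spreadsheet-style: every step written out, betas hard-coded here.

oracle_frs <- function(sex, age, tc_mmol, hdl_mmol, sbp, treated, smoker,
                       diabetic) {
  tc <- tc_mmol * 38.67
  hdl <- hdl_mmol * 38.67
  if (sex == "male") {
    lp <- 3.06117 * log(age) + 1.12370 * log(tc) - 0.93263 * log(hdl)
    lp <- lp + (if (treated) 1.99881 else 1.93303) * log(sbp)
    if (smoker) lp <- lp + 0.65451
    if (diabetic) lp <- lp + 0.57367
    risk <- 1 - 0.88936^exp(lp - 23.9802)
  } else {
    lp <- 2.32888 * log(age) + 1.20904 * log(tc) - 0.70833 * log(hdl)
    lp <- lp + (if (treated) 2.82263 else 2.76157) * log(sbp)
    if (smoker) lp <- lp + 0.52873
    if (diabetic) lp <- lp + 0.69154
    risk <- 1 - 0.95012^exp(lp - 26.1931)
  }
  100 * min(max(risk, 0), 1)
}

# -- BIC scoring, plain R reimplementation ----------------------------------

r_family_score <- function(node, parent_set, dataset) {
  n <- nrow(dataset$data)
  x <- factor(dataset$levels[[node]][dataset$data[, node]],
              levels = dataset$levels[[node]])
  r <- length(dataset$levels[[node]])
  if (length(parent_set) == 0) {
    counts <- table(x)
    ll <- sum(ifelse(counts > 0, counts * log(counts / n), 0))
    q <- 1
  } else {
    key <- do.call(paste, lapply(parent_set, function(p) dataset$data[, p]))
    tab <- table(key, x)
    rowtot <- rowSums(tab)
    ll <- 0
    for (i in seq_len(nrow(tab))) {
      for (j in seq_len(ncol(tab))) {
        if (tab[i, j] > 0) ll <- ll + tab[i, j] * log(tab[i, j] / rowtot[i])
      }
    }
    q <- prod(vapply(parent_set, function(p) length(dataset$levels[[p]]),
                     numeric(1)))
  }
  ll - log(n) / 2 * (r - 1) * q
}

r_network_score <- function(g, dataset) {
  sum(vapply(g$nodes, function(v) r_family_score(v, parents(g, v), dataset),
             numeric(1)))
}

# -- exhaustive DAG enumeration (3 labelled nodes -> 25 DAGs) ---------------

all_dags_3 <- function(nodes) {
  stopifnot(length(nodes) == 3)
  pairs <- t(combn(3, 2))
  out <- list()
  # each unordered pair: absent / forward / backward
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    states <- c(s1, s2, s3)
    arcs <- NULL
    for (k in 1:3) {
      if (states[k] == 1) arcs <- rbind(arcs, nodes[pairs[k, ]])
      if (states[k] == 2) arcs <- rbind(arcs, rev(nodes[pairs[k, ]]))
    }
    g <- tryCatch(dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1]] <- g
  }
  out
}

# -- independent joint-distribution enumerator ------------------------------
# Walks every full configuration with nested loops over a data frame grid and
# multiplies CPT entries looked up by level NAME (not index arithmetic).

oracle_joint <- function(net) {
  nodes <- net$dag$nodes
  grid <- expand.grid(net$levels[nodes], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    p <- 1
    for (v in nodes) {
      cpt <- net$cpts[[v]]
      idx <- as.list(c(grid[i, v],
                       unlist(grid[i, names(dimnames(cpt))[-1]])))
      p <- p * do.call(`[`, c(list(cpt), idx))
    }
    p
  }, numeric(1))
  cbind(grid, prob = probs)
}

oracle_conditional <- function(net, event_node, event_levels, evidence) {
  joint <- oracle_joint(net)
  keep <- rep(TRUE, nrow(joint))
  for (v in names(evidence)) keep <- keep & joint[[v]] == evidence[[v]]
  pe <- sum(joint$prob[keep])
  sum(joint$prob[keep & joint[[event_node]] %in% event_levels]) / pe
}

# -- small reusable networks ------------------------------------------------

chain_ab <- function(p_b_given_a = 0.9) {
  g <- dag(c("a", "b"), rbind(c("a", "b")))
  cpts <- list(
    a = array(c(0.5, 0.5), 2, dimnames = list(a = c("0", "1"))),
    b = array(c(p_b_given_a, 1 - p_b_given_a, 1 - p_b_given_a, p_b_given_a),
              c(2, 2), dimnames = list(b = c("0", "1"), a = c("0", "1"))))
  ground_truth_network(g, cpts)
}

# minimal valid cohort record for boundary tests
base_record <- function(...) {
  rec <- data.frame(
    age = 50, sex = "male", height = 170, weight = 65,
    bmi = 22.5, waist = 80, hip = 95, sbp = 115, dbp = 75, fpg = 5.0,
    tc = 4.5, hdl = 1.5, ldl = 2.8, tg = 1.2, uric_acid = 300,
    insulin = 8, creatinine = 0.9, hscrp = 1.0, hba1c = 5.4,
    smoker = 0, drinker = 0, on_antihypertensive = 0, on_lipid_lowering = 0,
    on_diabetes_treatment = 0, stringsAsFactors = FALSE)
  mods <- list(...)
  for (i in seq_along(mods)) rec[[names(mods)[i]]] <- mods[[i]]
  rec
}
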