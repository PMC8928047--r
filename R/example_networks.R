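# Reference ground-truth networks used to exercise structure learning,
# model averaging and inference against known answers.

#' Eight-node cardiometabolic toy network
#'
#' A known discrete network shaped after the layered dependence structure the
#' cohort analysis assumes: demographics drive behaviour and metabolic
#' status, metabolic status drives comorbidity markers, and age plus smoking
#' drive a three-level risk category. Effect sizes are deliberately strong so
#' that its arcs are recoverable from moderate samples.
#'
#' @return a `cvdbn_bn` with 8 nodes and 7 arcs.
#' @export
cardiometabolic_network <- function() {
  g <- dag(c("sex", "age", "smoking", "bmi", "mets", "hypertension",
             "chol", "risk"),
           rbind(c("sex", "smoking"), c("age", "mets"), c("bmi", "mets"),
                 c("mets", "hypertension"), c("mets", "chol"),
                 c("age", "risk"), c("smoking", "risk")))
  yn <- c("no", "yes")
  cpts <- list(
    sex = array(c(0.54, 0.46), 2, dimnames = list(sex = c("female", "male"))),
    age = array(c(0.45, 0.35, 0.20), 3,
                dimnames = list(age = c("30-49", "50-64", "65-74"))),
    smoking = array(c(0.95, 0.05, 0.40, 0.60), c(2, 2),
                    dimnames = list(smoking = yn, sex = c("female", "male"))),
    bmi = array(c(0.56, 0.34, 0.10), 3,
                dimnames = list(bmi = c("normal", "overweight", "obese"))),
    mets = array(
      # P(MU) rising in both age and BMI
      rbind(MH = 1 - c(0.15, 0.30, 0.40, 0.35, 0.55, 0.65, 0.55, 0.75, 0.85),
            MU = c(0.15, 0.30, 0.40, 0.35, 0.55, 0.65, 0.55, 0.75, 0.85)),
      dim = c(2, 3, 3),
      dimnames = list(mets = c("MH", "MU"), age = c("30-49", "50-64", "65-74"),
                      bmi = c("normal", "overweight", "obese"))),
    hypertension = array(c(0.85, 0.15, 0.35, 0.65), c(2, 2),
                         dimnames = list(hypertension = yn, mets = c("MH", "MU"))),
    chol = array(c(0.80, 0.20, 0.40, 0.60), c(2, 2),
                 dimnames = list(chol = yn, mets = c("MH", "MU"))),
    risk = array(
      c(0.90, 0.08, 0.02,   # 30-49, non-smoker
        0.55, 0.30, 0.15,   # 50-64, non-smoker
        0.25, 0.40, 0.35,   # 65-74, non-smoker
        0.70, 0.22, 0.08,   # 30-49, smoker
        0.30, 0.40, 0.30,   # 50-64, smoker
        0.10, 0.30, 0.60),  # 65-74, smoker
      dim = c(3, 3, 2),
      dimnames = list(risk = c("low", "moderate", "high"),
                      age = c("30-49", "50-64", "65-74"), smoking = yn)))
  ground_truth_network(g, cpts)
}

#' Random discrete network
#'
#' Draws a random DAG (uniform topological order, independent arc inclusion)
#' and random CPTs with Dirichlet(`alpha`) rows — the test battery behind the
#' sampler-versus-enumeration checks. `alpha > 1` keeps probabilities away
#' from 0 so importance weights stay well-behaved.
#'
#' @param n_nodes number of nodes (named x1, x2, ...).
#' @param seed integer seed.
#' @param max_parents cap on each node's parent count.
#' @param arc_prob probability that an admissible arc is included.
#' @param levels possible level counts per node (sampled uniformly).
#' @param alpha Dirichlet concentration for CPT rows.
#' @return a `cvdbn_bn`.
#' @export
random_discrete_network <- function(n_nodes, seed = 1L, max_parents = 2,
                                    arc_prob = 0.4, levels = 2:3, alpha = 2) {
  set.seed(seed)
  nodes <- paste0("x", seq_len(n_nodes))
  ord <- sample(nodes)
  nlev <- setNames(sample(levels, n_nodes, replace = TRUE), nodes)
  arcs <- NULL
  pa <- setNames(vector("list", n_nodes), nodes)
  for (i in seq_along(ord)) {
    v <- ord[i]
    cand <- if (i > 1) ord[seq_len(i - 1)] else character(0)
    cand <- cand[runif(length(cand)) < arc_prob]
    if (length(cand) > max_parents) cand <- sample(cand, max_parents)
    pa[[v]] <- cand
    if (length(cand) > 0) arcs <- rbind(arcs, cbind(cand, v))
  }
  g <- dag(nodes, arcs)
  cpts <- lapply(setNames(nodes, nodes), function(v) {
    r <- nlev[[v]]
    q <- prod(nlev[pa[[v]]])
    rows <- matrix(rgamma(r * q, shape = alpha), nrow = r)
    rows <- rows / rep(colSums(rows), each = r)
    dn <- c(list(paste0("l", seq_len(r))),
            lapply(pa[[v]], function(u) paste0("l", seq_len(nlev[[u]]))))
    names(dn) <- c(v, pa[[v]])
    array(rows, dim = c(r, nlev[pa[[v]]]), dimnames = dn)
  })
  ground_truth_network(g, cpts)
}
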