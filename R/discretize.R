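# Discretization of the derived cohort into the categorical variables the
# Bayesian network is learned over.

#' Default discretization map
#'
#' Bin edges and labels for the continuous variables entering the network.
#' Age uses the five decade groups the cohort is described by; eGFR, total
#' cholesterol, LDL-C and hsCRP use conventional clinical cut points (these
#' are package defaults, not values fixed by the reference analysis). All
#' bins are half-open `[lo, hi)`.
#'
#' @return named list; each element has `source` (cohort column), `breaks`
#'   and `labels`.
#' @export
default_discretization <- function() {
  list(
    age_group = list(source = "age", breaks = c(30, 40, 50, 60, 70, Inf),
                     labels = AGE_GROUP_LEVELS),
    egfr_bin = list(source = "egfr", breaks = c(0, 60, 90, Inf),
                    labels = c("reduced", "mild", "normal")),
    tc_bin = list(source = "tc", breaks = c(0, 5.2, 6.2, Inf),
                  labels = c("desirable", "borderline", "high")),
    ldl_bin = list(source = "ldl", breaks = c(0, 3.4, 4.1, Inf),
                   labels = c("optimal", "borderline", "high")),
    hscrp_bin = list(source = "hscrp", breaks = c(0, 1, 3, Inf),
                     labels = c("low", "average", "high")))
}

#' Default node set of the cohort network
#' @return character vector of node names.
#' @export
default_bn_nodes <- function() {
  c("sex", "age_group", "smoker", "drinker", "bmi_category",
    "metabolic_health", "hypertension", "diabetes", "dyslipidemia",
    "hyperuricemia", "egfr_bin", "tc_bin", "ldl_bin", "hscrp_bin",
    "frs_category")
}

#' Default layer ordering
#'
#' Demographics, then behaviours and the metabolic/obesity phenotype axes,
#' then comorbidities and biomarker bins, then the risk category. Compiled
#' into a blacklist: no arc may point from a later layer to an earlier one
#' (in particular, the risk category can never influence age).
#'
#' @return list of character vectors, earliest layer first.
#' @export
default_layers <- function() {
  list(c("sex", "age_group"),
       c("smoker", "drinker", "bmi_category", "metabolic_health"),
       c("hypertension", "diabetes", "dyslipidemia", "hyperuricemia",
         "egfr_bin", "tc_bin", "ldl_bin", "hscrp_bin"),
       "frs_category")
}

#' Default whitelist
#'
#' Metabolic health and BMI category are forced to point at the risk
#' category, embedding the causal reading of the obesity-phenotype effect.
#'
#' @return two-column matrix of arcs.
#' @export
default_whitelist <- function() {
  rbind(c("metabolic_health", "frs_category"),
        c("bmi_category", "frs_category"))
}

#' Default blacklist
#'
#' Beyond the layer-compiled direction constraints, the direct arc from sex
#' to the risk category is forbidden: the risk equation is sex-calibrated,
#' so an unconstrained search always finds a trivial direct dependence,
#' whereas the substantive question is how sex acts through its behavioural
#' and metabolic pathways (smoking in particular). Encoded as prior
#' knowledge, as in the reference network where sex reaches the risk
#' category only indirectly.
#'
#' @return two-column matrix of arcs.
#' @export
default_blacklist <- function() {
  rbind(c("sex", "frs_category"))
}

#' Discretize a scored cohort into a network-ready dataset
#'
#' Applies the discretization map to continuous variables, passes categorical
#' and 0/1 columns through as factors, and returns the complete-case dataset
#' over `nodes`. A value falling outside every bin raises an error naming
#' the row and variable.
#'
#' @param cohort phenotyped and scored cohort data frame.
#' @param map discretization map, as [default_discretization()].
#' @param nodes nodes to retain, default [default_bn_nodes()].
#' @return a `cvdbn_dataset`.
#' @export
discretize_cohort <- function(cohort, map = default_discretization(),
                              nodes = default_bn_nodes()) {
  cols <- list()
  levels <- list()
  for (v in nodes) {
    if (v %in% names(map)) {
      spec <- map[[v]]
      src <- cohort[[spec$source]]
      if (is.null(src)) {
        stop(sprintf("discretize: cohort lacks source column '%s' for node '%s'",
                     spec$source, v), call. = FALSE)
      }
      f <- cut(src, breaks = spec$breaks, labels = spec$labels, right = FALSE)
      if (anyNA(f)) {
        bad <- which(is.na(f))[1]
        stop(sprintf("discretize: value %.4g of '%s' (row %d) falls outside all bins",
                     src[bad], v, bad), call. = FALSE)
      }
      cols[[v]] <- f
      levels[[v]] <- spec$labels
    } else if (v %in% names(cohort)) {
      x <- cohort[[v]]
      if (is.logical(x)) x <- factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
      if (is.numeric(x)) {
        if (!all(x %in% c(0, 1))) {
          stop(sprintf("discretize: numeric node '%s' must be 0/1 or carry a bin spec", v),
               call. = FALSE)
        }
        x <- factor(ifelse(x == 1, "yes", "no"), levels = c("no", "yes"))
      }
      if (!is.factor(x)) x <- factor(x)
      cols[[v]] <- x
      levels[[v]] <- base::levels(x)
    } else {
      stop(sprintf("discretize: node '%s' not found in cohort", v), call. = FALSE)
    }
  }
  as_discrete_dataset(as.data.frame(cols, stringsAsFactors = FALSE), levels)
}
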