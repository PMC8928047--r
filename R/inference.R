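# Conditional probability queries on a fitted or ground-truth network:
# exact enumeration for small state spaces, likelihood weighting at scale.

check_query <- function(bn, event_node, event_levels, evidence) {
  nodes <- bn$dag$nodes
  if (!event_node %in% nodes) stop_field("event_node", paste("unknown node:", event_node))
  bad <- setdiff(event_levels, bn$levels[[event_node]])
  if (length(bad) > 0) {
    stop_field("event_levels", paste("unknown level(s):", paste(bad, collapse = ", ")))
  }
  if (length(evidence) > 0) {
    if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
      stop_field("evidence", "must be a named list (node = level)")
    }
    if (event_node %in% names(evidence)) {
      stop_field("evidence", "the event node cannot also carry evidence")
    }
    for (v in names(evidence)) {
      if (!v %in% nodes) stop_field("evidence", paste("unknown node:", v))
      if (!evidence[[v]] %in% bn$levels[[v]]) {
        stop_field("evidence", sprintf("unknown level '%s' for node '%s'",
                                       evidence[[v]], v))
      }
    }
  }
  invisible(TRUE)
}

#' Exact conditional probability by enumeration
#'
#' Computes `P(event | evidence)` by summing the factorised joint over every
#' completion of the non-evidence nodes — exact up to float rounding, and the
#' oracle the likelihood-weighting sampler is validated against. Intended for
#' small networks; the enumeration size is guarded by `max_states`.
#'
#' @param bn a `cvdbn_bn`.
#' @param event_node node whose event probability is queried.
#' @param event_levels one or more levels of `event_node` forming the event.
#' @param evidence named list of `node = level` assignments (may be empty).
#' @param max_states refuse to enumerate more joint completions than this.
#' @return the conditional probability (scalar in [0, 1]).
#' @export
exact_query <- function(bn, event_node, event_levels, evidence = list(),
                        max_states = 2^21) {
  stopifnot(inherits(bn, "cvdbn_bn"))
  check_query(bn, event_node, event_levels, evidence)
  nodes <- bn$dag$nodes
  free <- setdiff(nodes, names(evidence))
  rfree <- vapply(free, function(v) length(bn$levels[[v]]), numeric(1))
  if (prod(rfree) > max_states) {
    stop(sprintf("enumeration over %.3g states exceeds max_states = %g",
                 prod(rfree), max_states), call. = FALSE)
  }
  grid <- as.matrix(expand.grid(lapply(rfree, seq_len), KEEP.OUT.ATTRS = FALSE))
  conf <- matrix(1L, nrow(grid), length(nodes), dimnames = list(NULL, nodes))
  conf[, free] <- grid
  for (v in names(evidence)) {
    conf[, v] <- match(evidence[[v]], bn$levels[[v]])
  }
  p <- rep(1, nrow(conf))
  for (v in nodes) p <- p * cpt_prob(bn$cpts[[v]], v, conf)
  pe <- sum(p)
  if (pe <= 0) {
    stop("evidence has zero probability under the network; the conditional is undefined",
         call. = FALSE)
  }
  in_event <- conf[, event_node] %in% match(event_levels, bn$levels[[event_node]])
  sum(p[in_event]) / pe
}

# One likelihood-weighting pass returning the weighted distribution over the
# outcome node's levels; internal core of lw_query / reasoning_report.
lw_distribution <- function(bn, outcome_node, evidence, n_samples, seed) {
  nodes <- bn$dag$nodes
  conf <- matrix(1L, n_samples, length(nodes), dimnames = list(NULL, nodes))
  logw <- rep(0, n_samples)
  set.seed(seed)
  for (v in topological_sort(bn$dag)) {
    if (v %in% names(evidence)) {
      conf[, v] <- match(evidence[[v]], bn$levels[[v]])
      logw <- logw + log(cpt_prob(bn$cpts[[v]], v, conf))
    } else {
      conf[, v] <- cpt_draw(bn$cpts[[v]], conf, runif(n_samples))
    }
  }
  w <- exp(logw - max(logw))
  tw <- sum(w)
  if (!is.finite(tw) || tw <= 0) {
    stop("all likelihood weights are zero; the evidence is degenerate under the network",
         call. = FALSE)
  }
  r <- length(bn$levels[[outcome_node]])
  est <- vapply(seq_len(r), function(k) sum(w[conf[, outcome_node] == k]) / tw,
                numeric(1))
  setNames(est, bn$levels[[outcome_node]])
}

#' Approximate conditional probability by likelihood weighting
#'
#' Importance sampling for `P(event | evidence)`: evidence nodes are clamped
#' to their observed levels, every other node is forward-sampled, and each
#' sample is weighted by the product of the evidence nodes' conditional
#' probabilities given their sampled parents. Deterministic given `seed`.
#'
#' @inheritParams exact_query
#' @param n_samples number of weighted samples.
#' @param seed integer seed.
#' @return the estimated conditional probability.
#' @export
lw_query <- function(bn, event_node, event_levels, evidence = list(),
                     n_samples = 10000, seed = 1L) {
  stopifnot(inherits(bn, "cvdbn_bn"))
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop_field("n_samples", "must be a positive integer")
  }
  check_query(bn, event_node, event_levels, evidence)
  dist <- lw_distribution(bn, event_node, evidence, as.integer(n_samples), seed)
  sum(dist[event_levels])
}

#' Conditional probability with a Monte Carlo confidence interval
#'
#' Runs [lw_query()] on `replicates` independent sub-seeds and reports the
#' replicate mean with an empirical 2.5/97.5 percentile interval. This
#' captures the Monte Carlo error of the query itself; `method = "bootstrap"`
#' instead refits the CPTs on a nonparametric resample of `data` per
#' replicate, so the interval reflects parameter-estimation uncertainty.
#'
#' @inheritParams lw_query
#' @param replicates number of independent estimates (>= 2).
#' @param method `"sampling"` (Monte Carlo error) or `"bootstrap"` (refit the
#'   CPTs per data resample; requires `data`).
#' @param data the `cvdbn_dataset` behind `bn`; needed for the bootstrap mode.
#' @return data frame row with `point`, `ci_low`, `ci_high`, `replicates`,
#'   `n_samples`, `seed`.
#' @export
query_ci <- function(bn, event_node, event_levels, evidence = list(),
                     replicates = 30, n_samples = 10000, seed = 1L,
                     method = c("sampling", "bootstrap"), data = NULL) {
  method <- match.arg(method)
  if (!is.numeric(replicates) || replicates < 2) {
    stop_field("replicates", "needs at least 2 replicates")
  }
  ests <- vapply(seq_len(replicates), function(b) {
    sub <- derive_seed(seed, b)
    if (method == "sampling") {
      lw_query(bn, event_node, event_levels, evidence, n_samples, sub)
    } else {
      if (is.null(data)) stop_field("data", "required for method = 'bootstrap'")
      set.seed(sub)
      idx <- sample.int(nrow(data$data), nrow(data$data), replace = TRUE)
      refit <- suppressWarnings(
        fit_cpts(bn$dag, dataset_rows(data, idx),
                 smoothing = bn$smoothing %||% 0))
      lw_query(refit, event_node, event_levels, evidence, n_samples,
               derive_seed(sub, 1))
    }
  }, numeric(1))
  ci <- unname(quantile(ests, c(0.025, 0.975)))
  point <- mean(ests)
  data.frame(point = point, ci_low = min(ci[1], point),
             ci_high = max(ci[2], point), replicates = replicates,
             n_samples = n_samples, seed = seed)
}

#' Scenario sweep of conditional risk distributions
#'
#' Evaluates the conditional distribution of an outcome node (by default the
#' three-level 10-year CVD risk category) under each evidence scenario, with
#' Monte Carlo percentile intervals — the tabular analogue of
#' probability-given-evidence figures.
#'
#' @param bn a `cvdbn_bn`.
#' @param scenarios named list; each element is a named list of
#'   `node = level` evidence (an empty list queries the marginal).
#' @param outcome outcome node name.
#' @param replicates,n_samples,seed Monte Carlo settings as in [query_ci()].
#' @return data frame with one row per scenario x outcome level: `scenario`,
#'   `evidence`, `category`, `point`, `ci_low`, `ci_high`, `replicates`,
#'   `n_samples`, `seed`.
#' @export
reasoning_report <- function(bn, scenarios, outcome = "frs_category",
                             replicates = 30, n_samples = 10000, seed = 1L) {
  stopifnot(inherits(bn, "cvdbn_bn"))
  if (length(scenarios) == 0) {
    return(data.frame(scenario = character(0), evidence = character(0),
                      category = character(0), point = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      replicates = integer(0), n_samples = integer(0),
                      seed = integer(0)))
  }
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }
  out <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    ev <- scenarios[[s]]
    check_query(bn, outcome, bn$levels[[outcome]][1], ev)
    sseed <- derive_seed(seed, 1000 + s)
    reps <- t(vapply(seq_len(replicates), function(b) {
      lw_distribution(bn, outcome, ev, as.integer(n_samples),
                      derive_seed(sseed, b))
    }, numeric(length(bn$levels[[outcome]]))))
    ev_str <- if (length(ev) == 0) "" else
      paste(names(ev), unlist(ev), sep = "=", collapse = ", ")
    out[[s]] <- data.frame(
      scenario = names(scenarios)[s], evidence = ev_str,
      category = bn$levels[[outcome]],
      point = colMeans(reps),
      ci_low = apply(reps, 2, quantile, 0.025),
      ci_high = apply(reps, 2, quantile, 0.975),
      replicates = replicates, n_samples = n_samples, seed = seed,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
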