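# Shared representation of a discrete Bayesian network (structure + CPTs).
#
# CPTs follow the conventional array layout: the first dimension indexes the
# node's own levels, the remaining dimensions one parent each, and
# names(dimnames) records c(node, parents). Every slice over the first
# dimension is a probability vector.

validate_cpts <- function(g, cpts, tol = 1e-9) {
  for (v in g$nodes) {
    cpt <- cpts[[v]]
    if (is.null(cpt)) stop(sprintf("missing CPT for node '%s'", v), call. = FALSE)
    dn <- dimnames(cpt)
    if (is.null(dn) || is.null(names(dn))) {
      stop(sprintf("CPT for '%s' needs named dimnames (node then parents)", v),
           call. = FALSE)
    }
    if (names(dn)[1] != v) {
      stop(sprintf("first CPT dimension of '%s' must be the node itself", v),
           call. = FALSE)
    }
    pa_cpt <- names(dn)[-1]
    pa_dag <- parents(g, v)
    if (!setequal(pa_cpt, pa_dag)) {
      stop(sprintf("CPT parents of '%s' (%s) disagree with the graph (%s)", v,
                   paste(pa_cpt, collapse = ","), paste(pa_dag, collapse = ",")),
           call. = FALSE)
    }
    sums <- if (length(dim(cpt)) == 1) sum(cpt) else
      apply(cpt, seq_along(dim(cpt))[-1], sum)
    if (any(abs(sums - 1) > tol) || any(cpt < -tol)) {
      stop(sprintf("CPT rows of '%s' must be probability vectors summing to 1", v),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

new_bn <- function(g, cpts, extra = list()) {
  levels <- lapply(cpts, function(cpt) dimnames(cpt)[[1]])
  names(levels) <- names(cpts)
  structure(c(list(dag = g, cpts = cpts[g$nodes], levels = levels[g$nodes]),
              extra),
            class = "cvdbn_bn")
}

#' Define a discrete Bayesian network with known parameters
#'
#' Couples a [dag()] with one conditional probability table per node — the
#' ground-truth object that synthetic datasets are sampled from and the
#' reference against which learning and inference are tested.
#'
#' @param g a `cvdbn_dag`.
#' @param cpts named list of CPT arrays; for each node the first dimension
#'   spans its own levels, later dimensions its parents' levels, and
#'   `names(dimnames())` gives `c(node, parents)`. Every probability slice
#'   must sum to 1 within 1e-9.
#' @return an object of class `cvdbn_bn`.
#' @examples
#' g <- dag(c("a", "b"), rbind(c("a", "b")))
#' cpts <- list(
#'   a = array(c(0.5, 0.5), 2, dimnames = list(a = c("0", "1"))),
#'   b = array(c(0.9, 0.1, 0.1, 0.9), c(2, 2),
#'             dimnames = list(b = c("0", "1"), a = c("0", "1"))))
#' net <- ground_truth_network(g, cpts)
#' @export
ground_truth_network <- function(g, cpts) {
  stopifnot(inherits(g, "cvdbn_dag"))
  validate_cpts(g, cpts)
  new_bn(g, cpts)
}

#' @export
print.cvdbn_bn <- function(x, ...) {
  cat(sprintf("<cvdbn_bn> %d nodes, %d arcs%s\n", length(x$dag$nodes),
              nrow(x$dag$arcs),
              if (!is.null(x$n)) sprintf(" (fit to n = %d)", x$n) else ""))
  invisible(x)
}

# Linear parent-configuration index (1-based) for each row of an integer
# level matrix `conf` (columns named by node).
parent_config_index <- function(cpt, conf) {
  dims <- dim(cpt)
  pa <- names(dimnames(cpt))[-1]
  if (length(pa) == 0) return(rep(1L, nrow(conf)))
  idx <- rep(0L, nrow(conf))
  stride <- 1L
  for (j in seq_along(pa)) {
    idx <- idx + (conf[, pa[j]] - 1L) * stride
    stride <- stride * dims[j + 1]
  }
  idx + 1L
}

# P(node = conf[, node] | parents = conf[, parents]) for each row.
cpt_prob <- function(cpt, node, conf) {
  r <- dim(cpt)[1]
  pc <- parent_config_index(cpt, conf)
  as.numeric(cpt)[(pc - 1L) * r + conf[, node]]
}

# Vectorised categorical draw: one level per row of `conf`, given the node's
# parent columns and a vector of uniforms.
cpt_draw <- function(cpt, conf, u) {
  r <- dim(cpt)[1]
  M <- matrix(as.numeric(cpt), nrow = r)
  CM <- apply(M, 2, cumsum)
  if (is.null(dim(CM))) CM <- matrix(CM, nrow = r)
  pc <- parent_config_index(cpt, conf)
  cm <- CM[, pc, drop = FALSE]
  lev <- 1L + colSums(cm < matrix(u, nrow = r, ncol = length(u), byrow = TRUE))
  pmin(lev, r)  # guard the u ~ 1 edge against cumulative rounding
}

#' Sample a dataset from a known network
#'
#' Ancestral (topological-order forward) sampling from the network's joint
#' factorisation; the empirical joint converges to the network's as `n`
#' grows.
#'
#' @param net a `cvdbn_bn`.
#' @param n number of rows.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a `cvdbn_dataset` over the network's nodes and levels.
#' @export
generate_from_network <- function(net, n, seed = 1L) {
  stopifnot(inherits(net, "cvdbn_bn"))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop_field("n", "must be a nonnegative integer")
  }
  nodes <- net$dag$nodes
  conf <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
  set.seed(seed)
  for (v in topological_sort(net$dag)) {
    conf[, v] <- cpt_draw(net$cpts[[v]], conf, runif(n))
  }
  df <- as.data.frame(lapply(setNames(nodes, nodes), function(v) {
    factor(net$levels[[v]][conf[, v]], levels = net$levels[[v]])
  }))
  if (n == 0) {
    return(structure(list(data = conf, nodes = nodes, levels = net$levels),
                     class = "cvdbn_dataset"))
  }
  as_discrete_dataset(df, levels = net$levels)
}

#' Fit conditional probability tables on a fixed structure
#'
#' Maximum-likelihood (optionally Laplace-smoothed) estimation of one CPT per
#' node: each entry is `(count + smoothing) / (row total + smoothing * r)`.
#' With `smoothing = 0`, a parent configuration never observed in the data
#' gets a uniform distribution, with a warning.
#'
#' @param g a `cvdbn_dag` whose nodes all appear in `data`.
#' @param data a `cvdbn_dataset`.
#' @param smoothing nonnegative pseudo-count added to every cell.
#' @return a `cvdbn_bn` carrying fit metadata (`n`, `smoothing`).
#' @export
fit_cpts <- function(g, data, smoothing = 0) {
  stopifnot(inherits(g, "cvdbn_dag"), inherits(data, "cvdbn_dataset"))
  if (!is.numeric(smoothing) || smoothing < 0) {
    stop_field("smoothing", "must be nonnegative")
  }
  bad <- setdiff(g$nodes, data$nodes)
  if (length(bad) > 0) {
    stop_field("g", paste("node(s) absent from data:", paste(bad, collapse = ", ")))
  }
  empty_rows <- 0L
  cpts <- lapply(setNames(g$nodes, g$nodes), function(v) {
    pa <- parents(g, v)
    r <- length(data$levels[[v]])
    qdims <- vapply(pa, function(u) length(data$levels[[u]]), integer(1))
    q <- prod(qdims)
    dn <- c(list(data$levels[[v]]), data$levels[pa])
    names(dn) <- c(v, pa)
    # linear cell index per row
    pc <- rep(0L, nrow(data$data))
    stride <- 1L
    for (j in seq_along(pa)) {
      pc <- pc + (data$data[, pa[j]] - 1L) * stride
      stride <- stride * qdims[j]
    }
    cnt <- tabulate(pc * r + data$data[, v], nbins = r * q)
    cnt <- matrix(cnt, nrow = r)
    tot <- colSums(cnt)
    prob <- (cnt + smoothing) / rep(tot + smoothing * r, each = r)
    if (smoothing == 0 && any(tot == 0)) {
      empty_rows <<- empty_rows + sum(tot == 0)
      prob[, tot == 0] <- 1 / r
    }
    array(prob, dim = c(r, qdims), dimnames = dn)
  })
  if (empty_rows > 0) {
    warning(sprintf("%d unobserved parent configuration(s) fell back to uniform distributions",
                    empty_rows), call. = FALSE)
  }
  new_bn(g, cpts, extra = list(n = nrow(data$data), smoothing = smoothing))
}
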