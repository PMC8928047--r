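#' Bootstrap structure learning
#'
#' Learns one network per nonparametric bootstrap resample of the data, under
#' a common set of constraints — the model-averaging device used to assess
#' arc stability. Replicate `b` draws its row resample under the
#' deterministic sub-seed `derive_seed(seed, b)`, so any single replicate is
#' reproducible in isolation and results do not depend on execution order.
#'
#' @param data a `cvdbn_dataset`.
#' @param B number of bootstrap replicates (the reference analysis uses 300).
#' @param constraints a `cvdbn_constraints` or NULL.
#' @param params a `cvdbn_tabu_params`.
#' @param seed integer master seed.
#' @param resample set `FALSE` to learn every replicate from the original
#'   data (diagnostic mode; with `B = 1` this reduces to [tabu_search()]).
#' @return list of `B` `cvdbn_dag` objects, class `cvdbn_dag_list`.
#' @export
bootstrap_learn <- function(data, B, constraints = NULL,
                            params = tabu_params(), seed = 1L,
                            resample = TRUE) {
  stopifnot(inherits(data, "cvdbn_dataset"))
  if (!is.numeric(B) || length(B) != 1 || B < 1 || B != round(B)) {
    stop_field("B", "must be a positive integer")
  }
  n <- nrow(data$data)
  dags <- vector("list", B)
  for (b in seq_len(B)) {
    db <- if (resample) {
      set.seed(derive_seed(seed, b))
      dataset_rows(data, sample.int(n, n, replace = TRUE))
    } else data
    dags[[b]] <- tryCatch(
      tabu_search(db, constraints, params),
      error = function(e) {
        stop(sprintf("structure learning failed in bootstrap replicate %d: %s",
                     b, conditionMessage(e)), call. = FALSE)
      })
  }
  structure(dags, class = "cvdbn_dag_list")
}

#' Bootstrap arc strength and direction frequencies
#'
#' For every ordered node pair with any presence across the replicates:
#' `strength` is the fraction of networks containing the edge in either
#' orientation, and `direction` the fraction of those edge-containing
#' networks orienting it from -> to. Hence `direction(u,v) + direction(v,u)
#' = 1` wherever `strength > 0`, and a whitelisted arc has strength 1.
#'
#' @param dags a list of `cvdbn_dag` objects over a common node set.
#' @return data frame (from, to, strength, direction) of class
#'   `cvdbn_arc_strengths`, with attributes `B` and `nodes`; both
#'   orientations of each observed edge are listed.
#' @export
arc_strengths <- function(dags) {
  if (length(dags) < 1) stop_field("dags", "needs at least one network")
  nodes <- dags[[1]]$nodes
  for (g in dags) {
    if (!setequal(g$nodes, nodes)) {
      stop("all networks must share one node set", call. = FALSE)
    }
  }
  p <- length(nodes)
  dir_count <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (g in dags) {
    if (nrow(g$arcs) > 0) {
      dir_count[g$arcs] <- dir_count[g$arcs] + 1L
    }
  }
  B <- length(dags)
  either <- dir_count + t(dir_count)
  idx <- which(either > 0, arr.ind = TRUE)
  out <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                    strength = either[idx] / B,
                    direction = dir_count[idx] / either[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cvdbn_arc_strengths", "data.frame"),
            B = B, nodes = nodes)
}

#' Assemble an arc strength table from plain columns
#'
#' Used when reloading a serialized strength table.
#'
#' @param df data frame with columns from, to, strength, direction.
#' @param nodes full node set.
#' @param B replicate count behind the frequencies.
#' @return a `cvdbn_arc_strengths`.
#' @export
arc_strength_table <- function(df, nodes, B) {
  stopifnot(all(c("from", "to", "strength", "direction") %in% names(df)),
            B >= 1)
  if (any(df$strength < 0 | df$strength > 1)) {
    stop_field("strength", "must lie in [0, 1]")
  }
  structure(as.data.frame(df), class = c("cvdbn_arc_strengths", "data.frame"),
            B = B, nodes = nodes)
}

#' Threshold an arc strength table into a consensus network
#'
#' Retains an edge iff its strength is `>= threshold` (or strictly `>` with
#' `strict = TRUE`, matching a "strength above 0.85" rule), oriented by the
#' majority direction. If thresholding ever yields a directed cycle, the
#' weakest arc inside a cycle is dropped repeatedly until the result is
#' acyclic, with a loud warning — consensus cycles indicate genuinely
#' unstable directions.
#'
#' @param strengths a `cvdbn_arc_strengths`.
#' @param threshold retention threshold in [0, 1] (0.5 keeps edges appearing
#'   in at least half the replicates).
#' @param strict use strict inequality at the threshold?
#' @return a `cvdbn_dag` over the table's node set.
#' @export
averaged_network <- function(strengths, threshold = 0.5, strict = FALSE) {
  stopifnot(inherits(strengths, "cvdbn_arc_strengths"))
  if (!is.numeric(threshold) || length(threshold) != 1) {
    stop_field("threshold", "must be a numeric scalar")
  }
  nodes <- attr(strengths, "nodes")
  keep <- if (strict) strengths$strength > threshold else
    strengths$strength >= threshold
  df <- strengths[keep & strengths$direction > 0.5, , drop = FALSE]
  # a direction tie (exactly 0.5 both ways) is broken towards the
  # lexicographically smaller from-node, for determinism
  ties <- strengths[keep & strengths$direction == 0.5 &
                      strengths$from < strengths$to, , drop = FALSE]
  df <- rbind(df, ties)
  if (nrow(df) == 0) return(dag(nodes))
  df <- df[order(df$from, df$to), , drop = FALSE]
  arcs <- as.matrix(df[, c("from", "to")])
  strength <- df$strength
  repeat {
    gtry <- list(nodes = nodes, arcs = arcs)
    if (!is.null(topological_sort(gtry))) break
    cyc <- find_cycle(nodes, arcs)
    in_cycle <- paste(arcs[, 1], arcs[, 2]) %in% paste(cyc$from, cyc$to)
    victim <- which(in_cycle)[which.min(strength[in_cycle])]
    warning(sprintf("consensus network contained a cycle; dropped weakest arc %s -> %s (strength %.3f)",
                    arcs[victim, 1], arcs[victim, 2], strength[victim]),
            call. = FALSE)
    arcs <- arcs[-victim, , drop = FALSE]
    strength <- strength[-victim]
  }
  g <- dag(nodes, arcs)
  attr(g, "strength") <- setNames(strength, paste0(arcs[, 1], "->", arcs[, 2]))
  g
}

# Locate one directed cycle (as a data frame of arcs) by DFS; internal.
find_cycle <- function(nodes, arcs) {
  adj <- split(arcs[, 2], factor(arcs[, 1], levels = nodes))
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  cycle <- NULL
  visit <- function(u) {
    state[u] <<- 1L
    for (v in adj[[u]]) {
      if (!is.null(cycle)) return()
      if (state[v] == 0L) {
        parent[v] <<- u
        visit(v)
      } else if (state[v] == 1L) {
        path <- u
        while (path[1] != v) path <- c(parent[path[1]], path)
        cycle <<- data.frame(from = path, to = c(path[-1], v),
                             stringsAsFactors = FALSE)
        return()
      }
    }
    state[u] <<- 2L
  }
  for (u in nodes) {
    if (state[u] == 0L && is.null(cycle)) visit(u)
  }
  cycle
}
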