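#' Tabu search hyperparameters
#'
#' @param tabu_len number of most recent inverse moves kept forbidden.
#' @param max_iter hard iteration cap.
#' @param max_stall stop after this many consecutive moves that fail to
#'   improve the best score found.
#' @param restarts number of search starts; restarts beyond the first begin
#'   from a randomly perturbed copy of the incumbent best graph.
#' @param seed integer seed used only when `restarts > 1` (the base search is
#'   fully deterministic).
#' @return object of class `cvdbn_tabu_params`.
#' @export
tabu_params <- function(tabu_len = 10, max_iter = 10000, max_stall = 50,
                        restarts = 1, seed = 1L) {
  for (f in c("tabu_len", "max_iter", "max_stall", "restarts")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop_field(f, "must be a positive integer")
    }
  }
  structure(list(tabu_len = as.integer(tabu_len),
                 max_iter = as.integer(max_iter),
                 max_stall = as.integer(max_stall),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "cvdbn_tabu_params")
}

#' Score-based structure learning by tabu search
#'
#' Greedy local search over DAG space maximising the BIC network score.
#' Local moves are single-arc addition, deletion and reversal; after a move
#' is applied its inverse is placed on a short tabu list and is forbidden
#' unless taking it would beat the best score seen so far (aspiration).
#' Whitelisted arcs are fixed in the starting graph and never removed;
#' blacklisted arcs are never introduced. Ties between equal-scoring moves
#' break lexicographically by (operation, from, to), so the search is
#' deterministic for a fixed seed.
#'
#' @param data a `cvdbn_dataset`.
#' @param constraints a `cvdbn_constraints` (defaults to no constraints).
#' @param params a `cvdbn_tabu_params`.
#' @return a `cvdbn_dag` containing every whitelisted arc and no blacklisted
#'   arc, with attributes `score` (its BIC network score) and `iterations`.
#' @export
tabu_search <- function(data, constraints = NULL, params = tabu_params()) {
  stopifnot(inherits(data, "cvdbn_dataset"))
  nodes <- data$nodes
  if (is.null(constraints)) constraints <- arc_constraints(nodes)
  stopifnot(inherits(constraints, "cvdbn_constraints"))
  if (!setequal(constraints$nodes, nodes)) {
    stop_field("constraints", "node set must match the dataset")
  }
  ord <- nodes  # align constraint matrices with dataset column order
  wl <- constraints$whitelist[ord, ord]
  bl <- constraints$blacklist[ord, ord]
  nlev <- as.integer(nlevels_of(data))

  run_once <- function(start) {
    res <- tabu_search_cpp(data$data, nlev, start, wl, bl,
                           params$tabu_len, params$max_iter, params$max_stall)
    m <- res$amat
    dimnames(m) <- list(nodes, nodes)
    list(dag = dag_from_amat(m), score = res$score,
         iterations = res$iterations)
  }

  best <- run_once(wl)  # start from empty graph plus whitelist
  if (params$restarts > 1) {
    set.seed(params$seed)
    for (r in seq_len(params$restarts - 1)) {
      m <- amat(best$dag)
      free <- which(m & !wl, arr.ind = TRUE)
      if (nrow(free) > 0) {
        k <- min(nrow(free), 1 + stats::rbinom(1, nrow(free) - 1, 0.3))
        drop <- free[sample.int(nrow(free), k), , drop = FALSE]
        m[drop] <- FALSE
      }
      cand <- run_once(m)
      if (cand$score > best$score + 1e-9) best <- cand
    }
  }
  out <- best$dag
  attr(out, "score") <- best$score
  attr(out, "iterations") <- best$iterations
  out
}
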