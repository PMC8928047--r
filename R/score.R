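#' BIC family score of a node given a candidate parent set
#'
#' The decomposable objective driving structure learning: the maximised
#' multinomial log-likelihood of `node` given the observed parent
#' configurations, penalised by `log(n)/2 * (r - 1) * q` free parameters,
#' where `r` is the node's level count and `q` the product of the parents'
#' level counts. Zero-count cells contribute zero log-likelihood. Higher is
#' better; the score of a whole network is the sum of its family scores.
#'
#' @param node node name.
#' @param parent_set character vector of parent names (may be empty).
#' @param data a `cvdbn_dataset`.
#' @return the family score (scalar).
#' @examples
#' d <- as_discrete_dataset(data.frame(a = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)))
#' family_score("a", character(0), d)  # 6*log(.6) + 4*log(.4) - log(10)/2
#' @export
family_score <- function(node, parent_set, data) {
  stopifnot(inherits(data, "cvdbn_dataset"))
  if (!node %in% data$nodes) stop_field("node", paste("unknown node:", node))
  bad <- setdiff(parent_set, data$nodes)
  if (length(bad) > 0) {
    stop_field("parent_set", paste("unknown node(s):", paste(bad, collapse = ", ")))
  }
  if (node %in% parent_set) stop_field("parent_set", "a node cannot parent itself")
  nlev <- nlevels_of(data)
  family_score_cpp(data$data, as.integer(nlev),
                   match(node, data$nodes) - 1L,
                   as.integer(match(parent_set, data$nodes) - 1L))
}

#' BIC network score
#'
#' Sum of [family_score()] over every node with its parent set in `g`;
#' invariant under any reordering of the arc set, and equal for
#' Markov-equivalent structures (BIC is score-equivalent).
#'
#' @param g a `cvdbn_dag` whose nodes all appear in `data`.
#' @param data a `cvdbn_dataset`.
#' @return the network score (scalar).
#' @export
network_score <- function(g, data) {
  stopifnot(inherits(g, "cvdbn_dag"), inherits(data, "cvdbn_dataset"))
  bad <- setdiff(g$nodes, data$nodes)
  if (length(bad) > 0) {
    stop_field("g", paste("node(s) absent from data:", paste(bad, collapse = ", ")))
  }
  sum(vapply(g$nodes, function(v) family_score(v, parents(g, v), data),
             numeric(1)))
}
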