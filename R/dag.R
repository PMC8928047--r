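#' Directed acyclic graphs over named nodes
#'
#' A `cvdbn_dag` is the structure half of a discrete Bayesian network: a set of
#' named nodes and directed arcs, guaranteed acyclic at construction time.
#'
#' @param nodes character vector of node names (unique, non-empty).
#' @param arcs two-column character matrix or data frame (`from`, `to`); may be
#'   `NULL` or zero rows for the empty graph.
#' @return an object of class `cvdbn_dag` with elements `nodes` and `arcs`
#'   (two-column character matrix).
#' @examples
#' g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' parents(g, "c")
#' @export
dag <- function(nodes, arcs = NULL) {
  if (!is.character(nodes) || length(nodes) == 0 || anyDuplicated(nodes) ||
      any(!nzchar(nodes))) {
    stop_field("nodes", "must be unique non-empty node names")
  }
  if (is.null(arcs) || NROW(arcs) == 0) {
    arcs <- matrix(character(0), ncol = 2)
  } else {
    arcs <- as.matrix(arcs)
    storage.mode(arcs) <- "character"
    if (ncol(arcs) != 2) stop_field("arcs", "must have two columns (from, to)")
  }
  colnames(arcs) <- c("from", "to")
  rownames(arcs) <- NULL
  unknown <- setdiff(c(arcs), nodes)
  if (length(unknown) > 0) {
    stop_field("arcs", paste("unknown node(s):", paste(unknown, collapse = ", ")))
  }
  if (any(arcs[, 1] == arcs[, 2])) stop_field("arcs", "self-loops are not allowed")
  if (anyDuplicated(paste(arcs[, 1], arcs[, 2], sep = "\r"))) {
    stop_field("arcs", "duplicate arcs are not allowed")
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "cvdbn_dag")
  if (is.null(topological_sort(g))) {
    stop("arcs describe a cyclic graph; a DAG is required", call. = FALSE)
  }
  g
}

#' @export
print.cvdbn_dag <- function(x, ...) {
  cat(sprintf("<cvdbn_dag> %d nodes, %d arcs\n", length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs) > 0) {
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Adjacency matrix of a DAG
#'
#' @param g a `cvdbn_dag`.
#' @return logical matrix with `[u, v]` `TRUE` iff the arc u -> v is present.
#' @export
amat <- function(g) {
  p <- length(g$nodes)
  m <- matrix(FALSE, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$arcs) > 0) m[g$arcs] <- TRUE
  m
}

#' Build a DAG from an adjacency matrix
#'
#' @param m logical adjacency matrix with node names as dimnames.
#' @return a `cvdbn_dag`.
#' @export
dag_from_amat <- function(m) {
  nodes <- rownames(m)
  idx <- which(m, arr.ind = TRUE)
  arcs <- cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  dag(nodes, arcs)
}

#' Topological node ordering
#'
#' Kahn's algorithm; the acyclicity guarantee of every `cvdbn_dag` rests on it.
#'
#' @param g a `cvdbn_dag` (or a list with `nodes` and `arcs` not yet validated).
#' @return character vector of nodes in topological order, or `NULL` if the
#'   arc set is cyclic.
#' @export
topological_sort <- function(g) {
  nodes <- g$nodes
  arcs <- g$arcs
  indeg <- setNames(integer(length(nodes)), nodes)
  if (NROW(arcs) > 0) {
    tab <- table(arcs[, 2])
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  indeg <- indeg[!names(indeg) %in% avail]
  while (length(avail) > 0) {
    u <- avail[1]
    avail <- avail[-1]
    out <- c(out, u)
    if (NROW(arcs) > 0) {
      ch <- arcs[arcs[, 1] == u, 2]
      for (v in ch) {
        if (v %in% names(indeg)) {
          indeg[v] <- indeg[v] - 1L
          if (indeg[v] == 0L) {
            avail <- sort(c(avail, v))
            indeg <- indeg[names(indeg) != v]
          }
        }
      }
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' Parent set of a node
#'
#' @param g a `cvdbn_dag`.
#' @param node node name.
#' @return character vector of parents (possibly empty).
#' @export
parents <- function(g, node) {
  if (!node %in% g$nodes) stop_field("node", paste("unknown node:", node))
  g$arcs[g$arcs[, 2] == node, 1]
}

#' Structural Hamming distance between two DAGs
#'
#' With `skeleton = FALSE` counts arc insertions, deletions and orientation
#' flips; with `skeleton = TRUE` compares undirected adjacency only (the
#' appropriate yardstick for a score-equivalent criterion such as BIC, which
#' cannot distinguish members of a Markov equivalence class).
#'
#' @param g1,g2 two `cvdbn_dag` objects over the same node set.
#' @param skeleton compare undirected skeletons only?
#' @return integer distance.
#' @export
shd <- function(g1, g2, skeleton = FALSE) {
  if (!setequal(g1$nodes, g2$nodes)) {
    stop("graphs must share a node set", call. = FALSE)
  }
  key <- function(a) paste(a[, 1], a[, 2], sep = "\r")
  ukey <- function(a) {
    paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]), sep = "\r")
  }
  if (skeleton) {
    e1 <- unique(ukey(g1$arcs))
    e2 <- unique(ukey(g2$arcs))
    return(length(setdiff(e1, e2)) + length(setdiff(e2, e1)))
  }
  e1 <- key(g1$arcs)
  e2 <- key(g2$arcs)
  u1 <- ukey(g1$arcs)
  u2 <- ukey(g2$arcs)
  flips <- sum(u1 %in% u2 & !(e1 %in% e2))
  only1 <- sum(!(u1 %in% u2))
  only2 <- sum(!(u2 %in% u1))
  flips + only1 + only2
}

#' Read / write arc lists as CSV
#'
#' The on-disk interchange format for learned structures: a two-column CSV
#' with header `from,to`.
#'
#' @param g a `cvdbn_dag`.
#' @param path file path.
#' @param nodes for `read_arcs_csv`, the full node set (isolated nodes do not
#'   appear in an arc list).
#' @return `write_arcs_csv` returns `path` invisibly; `read_arcs_csv` a
#'   `cvdbn_dag`.
#' @export
write_arcs_csv <- function(g, path) {
  write.csv(as.data.frame(g$arcs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_arcs_csv
#' @export
read_arcs_csv <- function(path, nodes) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  dag(nodes, as.matrix(df[, c("from", "to")]))
}

#' Export a DAG in DOT format
#'
#' @param g a `cvdbn_dag`.
#' @param path file path.
#' @param edge_labels optional named numeric vector keyed `"from->to"` (for
#'   example bootstrap arc strengths) rendered as edge labels.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path, edge_labels = NULL) {
  lines <- c("digraph bn {", sprintf('  "%s";', g$nodes))
  if (nrow(g$arcs) > 0) {
    for (i in seq_len(nrow(g$arcs))) {
      key <- paste0(g$arcs[i, 1], "->", g$arcs[i, 2])
      lab <- if (!is.null(edge_labels) && key %in% names(edge_labels)) {
        sprintf(' [label="%.2f"]', edge_labels[[key]])
      } else ""
      lines <- c(lines, sprintf('  "%s" -> "%s"%s;', g$arcs[i, 1],
                                g$arcs[i, 2], lab))
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
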