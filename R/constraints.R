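#' Whitelist/blacklist arc constraints
#'
#' Prior knowledge for constrained structure learning. Whitelisted arcs must
#' appear in every learned graph; blacklisted arcs may never appear. An
#' optional ordered layering is compiled into the blacklist: every arc from a
#' later layer to an earlier layer is forbidden, so arc directions across
#' layers are fixed by design (the layering device used to orient, e.g.,
#' demographic -> metabolic -> risk-category arcs).
#'
#' @param nodes character vector of all node names.
#' @param whitelist,blacklist two-column matrices/data frames of arcs, or NULL.
#' @param layers optional list of character vectors, earliest layer first;
#'   must partition a subset of `nodes` (nodes absent from all layers are
#'   unconstrained by the layering).
#' @return object of class `cvdbn_constraints` with logical matrices
#'   `whitelist` and `blacklist` and the original `layers`.
#' @export
arc_constraints <- function(nodes, whitelist = NULL, blacklist = NULL,
                            layers = NULL) {
  p <- length(nodes)
  to_mat <- function(a, what) {
    m <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    if (!is.null(a) && NROW(a) > 0) {
      a <- as.matrix(a)
      storage.mode(a) <- "character"
      unknown <- setdiff(c(a), nodes)
      if (length(unknown) > 0) {
        stop_field(what, paste("unknown node(s):", paste(unknown, collapse = ", ")))
      }
      if (any(a[, 1] == a[, 2])) stop_field(what, "self-loops are not allowed")
      m[a] <- TRUE
    }
    m
  }
  wl <- to_mat(whitelist, "whitelist")
  bl <- to_mat(blacklist, "blacklist")
  if (!is.null(layers)) {
    flat <- unlist(layers)
    unknown <- setdiff(flat, nodes)
    if (length(unknown) > 0) {
      stop_field("layers", paste("unknown node(s):", paste(unknown, collapse = ", ")))
    }
    if (anyDuplicated(flat)) stop_field("layers", "a node may appear in one layer only")
    for (i in seq_along(layers)) {
      for (j in seq_len(i - 1)) {
        bl[layers[[i]], layers[[j]]] <- TRUE  # later -> earlier forbidden
      }
    }
  }
  if (any(wl & bl)) {
    both <- which(wl & bl, arr.ind = TRUE)
    stop(sprintf("inconsistent constraints: arc(s) %s are both whitelisted and blacklisted",
                 paste(paste(nodes[both[, 1]], nodes[both[, 2]], sep = "->"),
                       collapse = ", ")), call. = FALSE)
  }
  # the whitelist on its own must be realisable as a DAG
  widx <- which(wl, arr.ind = TRUE)
  if (nrow(widx) > 0) {
    warcs <- cbind(nodes[widx[, 1]], nodes[widx[, 2]])
    gtry <- list(nodes = nodes, arcs = warcs)
    if (is.null(topological_sort(gtry))) {
      stop("inconsistent constraints: whitelist arcs form a cycle", call. = FALSE)
    }
  }
  structure(list(nodes = nodes, whitelist = wl, blacklist = bl,
                 layers = layers), class = "cvdbn_constraints")
}

#' Audit a learned structure against its constraints
#'
#' Lists every whitelisted arc with its presence status and every blacklist
#' violation; a learned network passes iff all whitelisted arcs are present
#' and no blacklisted arc appears.
#'
#' @param g a `cvdbn_dag`.
#' @param constraints a `cvdbn_constraints`.
#' @return list with `whitelist` (data frame from,to,present), `violations`
#'   (data frame from,to) and `passed` (logical).
#' @export
audit_constraints <- function(g, constraints) {
  m <- amat(g)
  nodes <- constraints$nodes
  widx <- which(constraints$whitelist, arr.ind = TRUE)
  wl_report <- data.frame(from = nodes[widx[, 1]], to = nodes[widx[, 2]],
                          stringsAsFactors = FALSE)
  wl_report$present <- if (nrow(wl_report) > 0) {
    m[cbind(wl_report$from, wl_report$to)]
  } else logical(0)
  viol <- which(constraints$blacklist & m, arr.ind = TRUE)
  violations <- data.frame(from = nodes[viol[, 1]], to = nodes[viol[, 2]],
                           stringsAsFactors = FALSE)
  list(whitelist = wl_report, violations = violations,
       passed = all(wl_report$present) && nrow(violations) == 0)
}
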