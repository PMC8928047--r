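#' Complete-case discrete datasets
#'
#' The container consumed by all structure-learning and fitting code: named
#' nodes, an ordered level set per node, and an integer matrix of 1-based
#' level indices with no missing cells.
#'
#' @param x data frame of factors (or vectors coercible to factors).
#' @param levels optional named list fixing the level order per column;
#'   defaults to the factor levels observed.
#' @return object of class `cvdbn_dataset` with elements `data` (integer
#'   matrix n x p), `nodes`, `levels`.
#' @export
as_discrete_dataset <- function(x, levels = NULL) {
  if (!is.data.frame(x) || ncol(x) == 0) {
    stop_field("x", "must be a data frame with at least one column")
  }
  if (nrow(x) < 1) stop_field("x", "needs at least one row")
  nodes <- names(x)
  lev <- vector("list", length(nodes))
  names(lev) <- nodes
  m <- matrix(0L, nrow(x), length(nodes), dimnames = list(NULL, nodes))
  for (v in nodes) {
    want <- if (!is.null(levels) && v %in% names(levels)) levels[[v]] else NULL
    f <- if (is.factor(x[[v]]) && is.null(want)) x[[v]] else {
      factor(as.character(x[[v]]), levels = want %||% sort(unique(as.character(x[[v]]))))
    }
    if (anyNA(f)) {
      stop(sprintf("column '%s' has missing or out-of-level values; the dataset must be complete cases", v),
           call. = FALSE)
    }
    lev[[v]] <- base::levels(f)
    m[, v] <- as.integer(f)
  }
  structure(list(data = m, nodes = nodes, levels = lev),
            class = "cvdbn_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cvdbn_dataset <- function(x, ...) {
  cat(sprintf("<cvdbn_dataset> %d rows, %d nodes\n", nrow(x$data),
              length(x$nodes)))
  for (v in x$nodes) {
    cat(sprintf("  %s: %s\n", v, paste(x$levels[[v]], collapse = "/")))
  }
  invisible(x)
}

#' Number of levels per node
#' @param d a `cvdbn_dataset`.
#' @return named integer vector.
#' @export
nlevels_of <- function(d) {
  vapply(d$levels, length, integer(1))
}

# Subset rows (bootstrap resampling); internal.
dataset_rows <- function(d, idx) {
  structure(list(data = d$data[idx, , drop = FALSE], nodes = d$nodes,
                 levels = d$levels), class = "cvdbn_dataset")
}
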