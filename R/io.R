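# Plain-text serialization of analysis artifacts: strength tables, CPTs,
# fitted networks and run manifests.

#' Write / read an arc strength table as CSV
#'
#' @param strengths a `cvdbn_arc_strengths`.
#' @param path file path.
#' @param nodes,B node set and replicate count for the reader (stored in the
#'   CSV header comment by the writer is deliberately avoided: CSV stays
#'   plain).
#' @return the path (writer, invisibly) or a `cvdbn_arc_strengths` (reader).
#' @export
write_arc_strengths <- function(strengths, path) {
  write.csv(as.data.frame(strengths), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_arc_strengths
#' @export
read_arc_strengths <- function(path, nodes, B) {
  arc_strength_table(read.csv(path, stringsAsFactors = FALSE), nodes, B)
}

#' Serialize a network's CPTs to a plain-text file
#'
#' Layout: one block per node, introduced by `node <name> | <parents>`, then
#' one line per parent configuration: the parent levels (comma-separated,
#' `-` when parentless) followed by the node-level probabilities in level
#' order, at full double precision. [read_cpts()] restores the network
#' bit-exactly given the same structure.
#'
#' @param bn a `cvdbn_bn`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_cpts <- function(bn, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    pa <- names(dimnames(cpt))[-1]
    writeLines(sprintf("node %s | %s", v,
                       if (length(pa) == 0) "-" else paste(pa, collapse = ",")),
               con)
    writeLines(sprintf("levels %s", paste(dimnames(cpt)[[1]], collapse = ",")),
               con)
    r <- dim(cpt)[1]
    q <- length(cpt) / r
    M <- matrix(as.numeric(cpt), nrow = r)
    pa_levels <- dimnames(cpt)[-1]
    grid <- if (length(pa) == 0) matrix("-", 1, 1) else
      as.matrix(expand.grid(pa_levels, KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE))
    for (j in seq_len(q)) {
      writeLines(paste(paste(grid[j, ], collapse = ","),
                       paste(sprintf("%.17g", M[, j]), collapse = " "),
                       sep = " | "), con)
    }
  }
  invisible(path)
}

#' Restore a network from a structure and a CPT file
#'
#' @param g the `cvdbn_dag` the CPTs belong to.
#' @param path file written by [write_cpts()].
#' @return a `cvdbn_bn`.
#' @export
read_cpts <- function(g, path) {
  lines <- readLines(path)
  cpts <- list()
  i <- 1
  while (i <= length(lines)) {
    header <- strsplit(sub("^node ", "", lines[i]), " \\| ")[[1]]
    v <- header[1]
    pa <- if (header[2] == "-") character(0) else
      strsplit(header[2], ",")[[1]]
    lev <- strsplit(sub("^levels ", "", lines[i + 1]), ",")[[1]]
    i <- i + 2
    rows <- list()
    keys <- character(0)
    while (i <= length(lines) && !startsWith(lines[i], "node ")) {
      parts <- strsplit(lines[i], " \\| ")[[1]]
      keys <- c(keys, parts[1])
      rows[[length(rows) + 1]] <- as.numeric(strsplit(parts[2], " ")[[1]])
      i <- i + 1
    }
    M <- do.call(cbind, rows)
    pa_levels <- lapply(seq_along(pa), function(j) {
      unique(vapply(strsplit(keys, ","), `[`, character(1), j))
    })
    dn <- c(list(lev), pa_levels)
    names(dn) <- c(v, pa)
    cpts[[v]] <- array(M, dim = c(length(lev),
                                  vapply(pa_levels, length, integer(1))),
                       dimnames = dn)
  }
  ground_truth_network(g, cpts)
}

#' Write a fitted network (structure + CPTs) to a directory
#'
#' @param bn a `cvdbn_bn`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_fitted_bn <- function(bn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_arcs_csv(bn$dag, file.path(dir, "arcs.csv"))
  writeLines(bn$dag$nodes, file.path(dir, "nodes.txt"))
  write_cpts(bn, file.path(dir, "cpts.txt"))
  invisible(dir)
}

#' @rdname write_fitted_bn
#' @export
read_fitted_bn <- function(dir) {
  nodes <- readLines(file.path(dir, "nodes.txt"))
  g <- read_arcs_csv(file.path(dir, "arcs.csv"), nodes)
  read_cpts(g, file.path(dir, "cpts.txt"))
}

# Write all pipeline artifacts under a directory; internal to run_pipeline.
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$cohort, file.path(dir, "cohort_derived.csv"),
            row.names = FALSE)
  write_arc_strengths(result$strengths, file.path(dir, "arc_strengths.csv"))
  write_arcs_csv(result$net_averaged, file.path(dir, "network_averaged.csv"))
  write_arcs_csv(result$net_final, file.path(dir, "network_final.csv"))
  str_avg <- attr(result$net_averaged, "strength")
  write_dot(result$net_averaged, file.path(dir, "network_averaged.dot"), str_avg)
  write_dot(result$net_final, file.path(dir, "network_final.dot"),
            attr(result$net_final, "strength"))
  write_fitted_bn(result$fit, file.path(dir, "fitted_bn"))
  write.csv(result$report, file.path(dir, "reasoning_report.csv"),
            row.names = FALSE)
  write.csv(result$table_phenotype, file.path(dir, "table_phenotype.csv"),
            row.names = FALSE)
  write.csv(result$table_frs, file.path(dir, "table_frs.csv"),
            row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
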