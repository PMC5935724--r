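#' Flatten a network result to an edge table
#'
#' One row per selected edge with the viewer-ready attributes: endpoint
#' kinds, median delta-SCC, z, p, direction (gain/loss of correlation) and
#' `width = |median_delta|`, the attribute viewers map to line width so edge
#' thickness is proportional to the size of the correlation change.
#'
#' @param result A `network_result` (one element of an `ssn_result`'s
#'   `networks` list).
#' @return data.frame with columns `group`, `var_a`, `var_b`, `kind_a`,
#'   `kind_b`, `median_delta`, `z`, `p`, `direction`, `width`, sorted as the
#'   selection was.
#' @export
to_edge_table <- function(result) {
  stopifnot(inherits(result, "network_result"))
  e <- result$edges
  data.frame(group = rep(result$group, nrow(e)),
             var_a = e$var_a, var_b = e$var_b,
             kind_a = e$kind_a, kind_b = e$kind_b,
             median_delta = e$median_delta, z = e$z, p = e$p,
             direction = e$direction, width = abs(e$median_delta),
             stringsAsFactors = FALSE)
}

#' Write an edge table as TSV
#'
#' Numeric columns are written with 17 significant digits so a read-back
#' reproduces the values bit-exactly. An empty selection yields a
#' header-only file.
#'
#' @param result A `network_result`, or an `ssn_result` (all groups are
#'   concatenated).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_table <- function(result, path) {
  tab <- if (inherits(result, "ssn_result")) {
    do.call(rbind, lapply(result$networks, to_edge_table))
  } else {
    to_edge_table(result)
  }
  cols <- colnames(tab)
  header <- paste(cols, collapse = "\t")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    paste(vapply(cols, function(cn) {
      v <- tab[[cn]][i]
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Convert a network result to an igraph graph
#'
#' Nodes carry a `kind` attribute (`"mRNA"`/`"lipid"`); edges carry
#' `median_delta`, `z`, `p`, `direction` and `width`. By default only nodes
#' touched by a selected edge are included; `nodes = "all"` adds every panel
#' variable as a (possibly isolated) node.
#'
#' @param result A `network_result`.
#' @param nodes `"touched"` (default) or `"all"`.
#' @return An [igraph::graph] object.
#' @export
to_igraph <- function(result, nodes = c("touched", "all")) {
  stopifnot(inherits(result, "network_result"))
  nodes <- match.arg(nodes)
  e <- result$edges
  node_df <- result$nodes
  if (nodes == "touched") {
    touched <- unique(c(e$var_a, e$var_b))
    node_df <- node_df[node_df$variable %in% touched, , drop = FALSE]
  }
  edge_df <- data.frame(from = e$var_a, to = e$var_b,
                        median_delta = e$median_delta, z = e$z, p = e$p,
                        direction = e$direction, width = abs(e$median_delta),
                        stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                vertices = node_df)
}

#' Write a network result to graph files
#'
#' Supported formats: `"SIF"` (simple interaction format,
#' `var_a<TAB>delta_scc<TAB>var_b`, one line per edge) and `"GraphML"`
#' (full node and edge attributes, written via igraph, readable by
#' Cytoscape and other viewers).
#'
#' @param result A `network_result`.
#' @param path Output path.
#' @param format `"SIF"` or `"GraphML"` (case-insensitive).
#' @param nodes `"touched"` (default) or `"all"`; GraphML only (SIF has no
#'   isolated-node syntax).
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(result, path, format = c("SIF", "GraphML"),
                             nodes = c("touched", "all")) {
  stopifnot(inherits(result, "network_result"))
  if (length(format) == 1L && !format %in% c("SIF", "GraphML")) {
    fmt <- tolower(format)
    if (!fmt %in% c("sif", "graphml")) {
      stop("unsupported format '", format, "' (use SIF or GraphML)")
    }
    format <- if (fmt == "sif") "SIF" else "GraphML"
  } else {
    format <- match.arg(format)
  }
  nodes <- match.arg(nodes)
  if (format == "SIF") {
    e <- result$edges
    writeLines(paste(e$var_a, "delta_scc", e$var_b, sep = "\t"), path)
  } else {
    g <- to_igraph(result, nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
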