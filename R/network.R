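#' Closeness centrality and eccentricity of the pathway graph
#'
#' Works on the undirected skeleton of the interaction list. For a node `v`
#' in a connected component of size `m`, the closeness centrality is
#' `CC = (m - 1) / sum of shortest-path distances from v`, and the
#' eccentricity `E` is its largest shortest-path distance; an isolated node
#' has `CC = 0` and `E = 0` by convention. A disconnected graph is handled
#' per component, with a warning.
#'
#' @param model a `pathway_model` (or an igraph object).
#' @return object of class `pathway_graph`: data.frame with `node`, `CC`,
#'   `E`, `component`; the igraph skeleton is in `attr(, "graph")`.
#' @export
graph_metrics <- function(model) {
  g <- if (inherits(model, "igraph")) {
    model
  } else {
    stopifnot(inherits(model, "pathway_model"))
    igraph::graph_from_data_frame(
      model$edges[, c("source", "target")],
      directed = FALSE,
      vertices = data.frame(name = model$nodes$name)
    )
  }
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("graph is disconnected: metrics computed per component")
  }
  d <- igraph::distances(g)
  nodes <- igraph::V(g)$name
  cc <- numeric(length(nodes))
  ecc <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    same <- comp$membership == comp$membership[i]
    di <- d[i, same]
    di <- di[is.finite(di) & di > 0]
    if (length(di) == 0) {
      cc[i] <- 0
      ecc[i] <- 0
    } else {
      cc[i] <- length(di) / sum(di)
      ecc[i] <- max(di)
    }
  }
  out <- data.frame(node = nodes, CC = cc, E = ecc,
                    component = comp$membership[seq_along(nodes)],
                    stringsAsFactors = FALSE)
  structure(out, class = c("pathway_graph", "data.frame"), graph = g)
}

#' Select validation nodes by centrality
#'
#' Ranks the eligible nodes (not used for calibration, and, when
#' `measured` is given, carrying an RPPA measurement) by closeness
#' centrality, then eccentricity, then name, and returns the top `k`. The
#' lexicographic CC-then-E order operationalizes "higher closeness
#' centrality and eccentricity".
#'
#' @param graph a `pathway_graph` from [graph_metrics()].
#' @param k number of nodes to select.
#' @param exclude calibration nodes (never selected).
#' @param measured optional character vector restricting eligibility to
#'   RPPA-measured nodes.
#' @return character vector of `k` node names, in rank order.
#' @export
select_validation_nodes <- function(graph, k, exclude = character(0),
                                    measured = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (k < 0) stop("k must be non-negative")
  eligible <- graph[!graph$node %in% exclude, , drop = FALSE]
  if (!is.null(measured)) {
    eligible <- eligible[eligible$node %in% measured, , drop = FALSE]
  }
  if (nrow(eligible) == 0) stop("no eligible nodes after exclusions")
  if (k > nrow(eligible)) {
    stop("k exceeds the ", nrow(eligible), " eligible nodes")
  }
  if (k == 0) return(character(0))
  ord <- order(-eligible$CC, -eligible$E, eligible$node)
  eligible$node[ord][seq_len(k)]
}
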