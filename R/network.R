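new_distortion_network <- function(graph, config = NULL) {
  structure(list(graph = graph, config = config), class = "distortion_network")
}

#' Build the co-occurrence network from significant pairs
#'
#' One undirected edge per significant pair, weighted by lift and carrying
#' the observed count and chi-square p-value as attributes. The graph is
#' simple: duplicate pairs in the input are a contract violation and raise
#' an error.
#'
#' @param pairs Data frame of significant pairs (as from [filter_edges()])
#'   with columns `label_i`, `label_j`, `lift`, `observed`, `p_value`.
#' @param isolate_policy `"drop"` (nodes are labels incident to at least
#'   one edge; default) or `"keep"` (all taxonomy labels become nodes).
#' @param nodes Node set used under `"keep"`; defaults to
#'   [default_taxonomy()].
#' @param validate Check the simple-graph contract (default `TRUE`).
#' @return An object of class `distortion_network` wrapping an igraph
#'   graph, with the filtering configuration as provenance.
#' @export
build_network <- function(pairs, isolate_policy = c("drop", "keep"),
                          nodes = default_taxonomy(), validate = TRUE) {
  isolate_policy <- match.arg(isolate_policy)
  if (nrow(pairs) > 0L) {
    key <- paste(pmin(pairs$label_i, pairs$label_j),
                 pmax(pairs$label_i, pairs$label_j), sep = "\r")
    if (validate && anyDuplicated(key)) {
      stop("duplicate pair in input violates the simple-graph contract")
    }
    if (validate && any(pairs$label_i == pairs$label_j)) {
      stop("self-pair in input violates the simple-graph contract")
    }
  }
  edge_df <- data.frame(
    from = pairs$label_i, to = pairs$label_j,
    weight = pairs$lift, count = pairs$observed,
    p_value = if (!is.null(pairs$p_value)) pairs$p_value else NA_real_,
    stringsAsFactors = FALSE
  )
  vertices <- if (isolate_policy == "keep") {
    data.frame(name = nodes, stringsAsFactors = FALSE)
  } else {
    data.frame(name = sort(unique(c(pairs$label_i, pairs$label_j))),
               stringsAsFactors = FALSE)
  }
  gr <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                      vertices = vertices)
  new_distortion_network(gr, config = attr(pairs, "config"))
}

#' @export
print.distortion_network <- function(x, ...) {
  cat(sprintf("<distortion_network> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node names of a network
#' @param g A `distortion_network`.
#' @return Character vector of node labels.
#' @export
network_nodes <- function(g) igraph::V(g$graph)$name

#' Edge table of a network
#' @param g A `distortion_network`.
#' @return Data frame with columns `label_i`, `label_j`, `lift`,
#'   `observed`, `p_value`.
#' @export
network_edges <- function(g) {
  if (igraph::ecount(g$graph) == 0L) {
    return(data.frame(label_i = character(), label_j = character(),
                      lift = numeric(), observed = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(g$graph)
  ea <- igraph::edge_attr(g$graph)
  data.frame(label_i = el[, 1], label_j = el[, 2],
             lift = ea$weight,
             observed = if (!is.null(ea$count)) ea$count else NA_integer_,
             p_value = if (!is.null(ea$p_value)) ea$p_value else NA_real_,
             stringsAsFactors = FALSE)
}

# local clustering with the convention that degree < 2 nodes have
# coefficient 0 (so the average runs over all nodes)
local_clustering <- function(graph) {
  lc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0
  stats::setNames(lc, igraph::V(graph)$name)
}

#' Global topology metrics of a distortion network
#'
#' Density is the realized fraction of possible edges; clustering is the
#' average local (unweighted) clustering coefficient over all nodes, with
#' degree < 2 nodes contributing 0 (the global transitivity is also
#' reported); assortativity is the Pearson degree-assortativity over edge
#' endpoints, reported as `NA` when undefined (e.g. regular graphs, where
#' endpoint degrees have zero variance).
#'
#' @param g A `distortion_network` with at least two nodes.
#' @return List of class `network_topology`: `n_nodes`, `n_edges`,
#'   `density`, `avg_clustering`, `global_transitivity`, `assortativity`.
#' @export
network_topology <- function(g) {
  gr <- g$graph
  nv <- igraph::vcount(gr)
  if (nv < 2L) stop("topology metrics require at least two nodes")
  lc <- local_clustering(gr)
  assort <- suppressWarnings(igraph::assortativity_degree(gr))
  if (!is.finite(assort)) assort <- NA_real_
  gt <- igraph::transitivity(gr, type = "global")
  if (!is.finite(gt)) gt <- NA_real_
  structure(
    list(n_nodes = nv, n_edges = igraph::ecount(gr),
         density = igraph::edge_density(gr),
         avg_clustering = mean(lc),
         global_transitivity = gt,
         assortativity = assort),
    class = "network_topology"
  )
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(
    "N = %d nodes, E = %d edges; density %.3f, clustering %.3f, assortativity %s\n",
    x$n_nodes, x$n_edges, x$density, x$avg_clustering,
    ifelse(is.na(x$assortativity), "NA", sprintf("%.3f", x$assortativity))))
  invisible(x)
}

#' Per-node centrality metrics
#'
#' Degree (edge count), weighted degree (sum of incident lift weights),
#' normalized betweenness with edge distances 1/lift (stronger
#' associations are shorter paths; normalization by (n-1)(n-2)/2), and the
#' unweighted local clustering coefficient (0 for nodes of degree < 2).
#'
#' @param g A non-empty `distortion_network`.
#' @return Data frame of class `centrality_report`, one row per node,
#'   columns `node`, `degree`, `weighted_degree`, `betweenness`,
#'   `local_clustering`.
#' @export
node_centralities <- function(g) {
  gr <- g$graph
  if (igraph::vcount(gr) == 0L) stop("centralities require a non-empty network")
  w <- igraph::E(gr)$weight
  btw <- if (igraph::vcount(gr) > 2L) {
    igraph::betweenness(gr, weights = if (length(w)) 1 / w else NULL,
                        normalized = TRUE)
  } else {
    stats::setNames(rep(0, igraph::vcount(gr)), igraph::V(gr)$name)
  }
  out <- data.frame(
    node = igraph::V(gr)$name,
    degree = as.integer(igraph::degree(gr)),
    weighted_degree = igraph::strength(gr, weights = w),
    betweenness = as.numeric(btw),
    local_clustering = as.numeric(local_clustering(gr)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("centrality_report", class(out))
  out
}

#' Top-k hub nodes
#'
#' Ranks nodes by degree, breaking ties by weighted degree (descending)
#' and then label lexicographic order. If `k` exceeds the node count, all
#' nodes are returned.
#'
#' @param x A `centrality_report` (from [node_centralities()]) or a
#'   `distortion_network`.
#' @param k Number of hubs (default 5).
#' @return Character vector of node labels, ranked.
#' @export
top_hubs <- function(x, k = 5L) {
  report <- if (inherits(x, "distortion_network")) node_centralities(x) else x
  ord <- order(-report$degree, -report$weighted_degree, report$node)
  report$node[ord][seq_len(min(k, nrow(report)))]
}

#' Lift-weighted adjacency matrix of a network
#'
#' Square symmetric matrix over a fixed node set (default the full
#' taxonomy, so matrices from different corpora are conformable); absent
#' edges are 0. `convention = "binary"` records edge presence instead of
#' lift.
#'
#' @param g A `distortion_network`.
#' @param nodes Node set / ordering of the matrix rows and columns.
#' @param convention `"lift_weighted"` (default) or `"binary"`.
#' @return Numeric matrix with zero diagonal.
#' @export
network_adjacency <- function(g, nodes = default_taxonomy(),
                              convention = c("lift_weighted", "binary")) {
  convention <- match.arg(convention)
  a <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ed <- network_edges(g)
  if (nrow(ed) > 0L) {
    if (!all(c(ed$label_i, ed$label_j) %in% nodes)) {
      stop("network contains nodes outside the requested node set")
    }
    val <- if (convention == "lift_weighted") ed$lift else 1
    a[cbind(ed$label_i, ed$label_j)] <- val
    a[cbind(ed$label_j, ed$label_i)] <- val
  }
  a
}
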