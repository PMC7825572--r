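.as_igraph <- function(network) {
  if (inherits(network, "igraph")) return(network)
  if (inherits(network, "cooc_network")) return(network_igraph(network))
  stop("expected a cooc_network or igraph object")
}

#' Topology summary of a co-occurrence network
#'
#' The seven standard indices as computed by Cytoscape's NetworkAnalyzer:
#' node and edge counts; clustering coefficient (mean local clustering over
#' nodes of degree >= 2, or over all nodes with `all_nodes = TRUE`);
#' network diameter (maximum finite shortest-path distance — the paper's
#' graphs are disconnected, so infinite distances are ignored);
#' shortest-path count (ordered connected pairs, always even by symmetry);
#' average number of neighbors 2E/N; and graph density 2E/(N(N-1)).
#'
#' @param network a `cooc_network` or undirected igraph graph (simple).
#' @param all_nodes include degree-<2 nodes (as zeros) in the clustering
#'   coefficient average.
#' @return a `topology_report` list with fields `nodes`, `edges`,
#'   `clustering_coefficient`, `network_diameter`, `shortest_paths`,
#'   `avg_neighbors`, `graph_density`.
#' @export
topology_report <- function(network, all_nodes = FALSE) {
  g <- .as_igraph(network)
  stopifnot(igraph::is_simple(g), !igraph::is_directed(g))
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  if (N == 0L) {
    return(structure(list(nodes = 0L, edges = 0L, clustering_coefficient = 0,
                          network_diameter = 0, shortest_paths = 0L,
                          avg_neighbors = 0, graph_density = 0),
                     class = "topology_report"))
  }
  deg <- igraph::degree(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc <- if (all_nodes) mean(loc)
        else if (any(deg >= 2)) mean(loc[deg >= 2]) else 0
  D <- igraph::distances(g)
  finite_off <- is.finite(D) & row(D) != col(D)
  diam <- if (any(finite_off)) max(D[finite_off]) else 0
  structure(list(nodes = N, edges = E,
                 clustering_coefficient = cc,
                 network_diameter = diam,
                 shortest_paths = sum(finite_off),
                 avg_neighbors = if (N > 0) 2 * E / N else 0,
                 graph_density = if (N > 1) 2 * E / (N * (N - 1)) else 0),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "nodes %d | edges %d | clustering %.3f | diameter %g | shortest paths %d | avg neighbors %.3f | density %.3f\n",
    x$nodes, x$edges, x$clustering_coefficient, x$network_diameter,
    x$shortest_paths, x$avg_neighbors, x$graph_density))
  invisible(x)
}

#' Per-node degree, closeness and betweenness centralities
#'
#' Conventions follow NetworkAnalyzer: closeness(n) = (number of nodes
#' reachable from n) / (sum of finite distances from n), i.e. computed
#' within n's connected component (isolated nodes score 0); betweenness is
#' the shortest-path betweenness with pair dependencies split equally among
#' all shortest paths, normalized to [0, 1] by 2 / ((N'-1)(N'-2)) with N'
#' the node's component size (components of size <= 2 score 0).
#'
#' @param network a `cooc_network` or igraph graph.
#' @return data.frame with columns `id`, `degree`, `closeness`,
#'   `betweenness`.
#' @export
node_centralities <- function(network) {
  g <- .as_igraph(network)
  N <- igraph::vcount(g)
  ids <- if (!is.null(igraph::V(g)$name)) igraph::V(g)$name
         else as.character(seq_len(N))
  if (N == 0L)
    return(data.frame(id = character(0), degree = integer(0),
                      closeness = numeric(0), betweenness = numeric(0)))
  deg <- unname(igraph::degree(g))
  D <- igraph::distances(g)
  reach <- rowSums(is.finite(D) & row(D) != col(D))
  dsum <- apply(D, 1, function(d) sum(d[is.finite(d) & d > 0]))
  clo <- ifelse(dsum > 0, reach / dsum, 0)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  btw_raw <- unname(igraph::betweenness(g, directed = FALSE))
  norm <- ifelse(csize > 2, 2 / ((csize - 1) * (csize - 2)), 0)
  data.frame(id = ids, degree = deg, closeness = unname(clo),
             betweenness = btw_raw * norm, stringsAsFactors = FALSE)
}

#' Keystone-taxon criteria
#'
#' A keystone taxon is a node jointly satisfying a degree condition, a
#' closeness condition and a betweenness condition.  Comparison modes cover
#' both styles used in practice: strict (">" / "<"), inclusive, and exact
#' equality (the ammonia-oxidizing archaea network's "degree = 5,
#' closeness = 1, betweenness = 0" rule).
#'
#' @param degree_min,closeness_min,betweenness_max numeric thresholds.
#' @param degree_cmp,closeness_cmp one of `"gt"`, `"ge"`, `"eq"`.
#' @param betweenness_cmp one of `"lt"`, `"le"`, `"eq"`.
#' @return a `keystone_criteria` list.
#' @export
keystone_criteria <- function(degree_min, closeness_min, betweenness_max,
                              degree_cmp = c("gt", "ge", "eq"),
                              closeness_cmp = c("gt", "ge", "eq"),
                              betweenness_cmp = c("lt", "le", "eq")) {
  stopifnot(degree_min >= 0, closeness_min >= 0, closeness_min <= 1,
            betweenness_max >= 0, betweenness_max <= 1)
  structure(list(degree_min = degree_min, closeness_min = closeness_min,
                 betweenness_max = betweenness_max,
                 degree_cmp = match.arg(degree_cmp),
                 closeness_cmp = match.arg(closeness_cmp),
                 betweenness_cmp = match.arg(betweenness_cmp)),
            class = "keystone_criteria")
}

#' Built-in keystone presets per marker gene
#'
#' `"AOA"`: degree = 5, closeness = 1, betweenness = 0 (exact);
#' `"nirS"`: degree > 10, closeness > 0.354, betweenness < 0.103;
#' `"nosZ"`: degree > 10, closeness > 0.311, betweenness < 0.096.
#'
#' @param name preset name.
#' @return a [keystone_criteria()].
#' @export
keystone_preset <- function(name = c("AOA", "nirS", "nosZ")) {
  switch(match.arg(name),
    AOA = keystone_criteria(5, 1, 0, "eq", "eq", "eq"),
    nirS = keystone_criteria(10, 0.354, 0.103, "gt", "gt", "lt"),
    nosZ = keystone_criteria(10, 0.311, 0.096, "gt", "gt", "lt"))
}

.cmp <- function(x, thr, mode) {
  switch(mode, gt = x > thr, ge = x >= thr, eq = x == thr,
         lt = x < thr, le = x <= thr)
}

#' Identify keystone taxa in a network
#'
#' Returns the taxon nodes (metadata-class nodes are excluded) satisfying
#' all three centrality conditions of `criteria`.
#'
#' @param network a `cooc_network` or igraph graph.
#' @param criteria a [keystone_criteria()] or a [keystone_preset()] name.
#' @return data.frame of keystone nodes with their centralities.
#' @export
keystone_taxa <- function(network, criteria) {
  if (is.character(criteria)) criteria <- keystone_preset(criteria)
  stopifnot(inherits(criteria, "keystone_criteria"))
  cent <- node_centralities(network)
  if (inherits(network, "cooc_network") && nrow(network$nodes)) {
    cls <- network$nodes$node_class[match(cent$id, network$nodes$id)]
    cent <- cent[is.na(cls) | cls != "metadata", , drop = FALSE]
  }
  keep <- .cmp(cent$degree, criteria$degree_min, criteria$degree_cmp) &
    .cmp(cent$closeness, criteria$closeness_min, criteria$closeness_cmp) &
    .cmp(cent$betweenness, criteria$betweenness_max, criteria$betweenness_cmp)
  cent[keep, , drop = FALSE]
}

#' Minimum-size gate for topology analysis
#'
#' Networks with fewer than `min_nodes` nodes (default 10) are excluded
#' from topology/keystone characterization, mirroring the exclusion of
#' very small networks from downstream analysis.
#'
#' @param network a `cooc_network` or igraph graph.
#' @param min_nodes inclusion threshold.
#' @return logical: TRUE if the network is large enough; the verdict and
#'   node count are attached as attributes `"n_nodes"` and `"reason"`.
#' @export
size_gate <- function(network, min_nodes = 10L) {
  n <- if (inherits(network, "cooc_network")) nrow(network$nodes)
       else igraph::vcount(.as_igraph(network))
  ok <- n >= min_nodes
  structure(ok, n_nodes = n,
            reason = if (ok) "included"
                     else sprintf("excluded: %d nodes < %d", n, min_nodes))
}
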