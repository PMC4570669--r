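# Weighted paths, centralities, central/peripheral partitions, Louvain
# communities and the per-network statistics panel.

check_positive_weights <- function(net) {
  if (nrow(net$edges) && any(!is.finite(net$edges$weight) | net$edges$weight <= 0))
    stop("all edge weights must be positive and finite")
}

#' Pairwise shortest-path distances under the reciprocal-weight metric
#'
#' The length of a path is the sum of reciprocal edge weights along it
#' (strong edges are short); distances are the Dijkstra minima, infinite
#' across components.
#'
#' @param net a `fold_network`.
#' @return symmetric numeric matrix of distances over the node universe.
#' @export
shortest_path_matrix <- function(net) {
  check_positive_weights(net)
  g <- as_igraph(net)
  w <- if (igraph::ecount(g)) 1 / igraph::E(g)$weight else NULL
  igraph::distances(g, weights = w, algorithm = "dijkstra")
}

#' Weighted node centralities
#'
#' Degree, closeness and betweenness in the weighted-network sense:
#' \eqn{C_D(i) = \sum_j w_{ij}} (sum of incident edge weights);
#' \eqn{C_C(i) = \sum_{j \ne i} 1/d(i,j)} summed over nodes in the same
#' connected component (reciprocal-weight distances); and
#' \eqn{C_B(i) = \sum_{j,k \ne i} \sigma_{jk}(i)/\sigma_{jk}} over unordered
#' pairs, with shortest paths under the same metric. Closeness and
#' betweenness are thereby computed within each connected component
#' separately.
#'
#' @param net a `fold_network`.
#' @return data.frame `node`, `component`, `n_neighbors`, `degree`,
#'   `closeness`, `betweenness`.
#' @export
centralities <- function(net) {
  check_positive_weights(net)
  g <- as_igraph(net)
  has_edges <- igraph::ecount(g) > 0
  w <- if (has_edges) igraph::E(g)$weight else NULL
  comp <- igraph::components(g)$membership
  cd <- if (has_edges) igraph::strength(g, weights = w) else
    setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  nn <- igraph::degree(g)
  D <- igraph::distances(g, weights = if (has_edges) 1 / w else NULL,
                         algorithm = "dijkstra")
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  cc <- rowSums(inv)
  cb <- if (has_edges) igraph::betweenness(g, weights = 1 / w) else
    rep(0, igraph::vcount(g))
  data.frame(node = igraph::V(g)$name, component = unname(comp),
             n_neighbors = unname(nn), degree = unname(cd),
             closeness = unname(cc), betweenness = unname(cb),
             stringsAsFactors = FALSE, row.names = NULL)
}

# top-k selection including boundary ties: all nodes whose value ties the
# k-th ranked value, k = ceiling(frac * n)
top_frac_nodes <- function(nodes, values, frac) {
  n <- length(values)
  if (n == 0) return(character(0))
  k <- ceiling(frac * n)
  cut <- sort(values, decreasing = TRUE)[k]
  nodes[values >= cut]
}

#' Central and peripheral node sets per centrality measure
#'
#' Central folds are the top 30% of nodes ranked by each measure (boundary
#' ties included). Peripheral folds: by closeness, the bottom 30%; by
#' degree, nodes with at most one neighbour; by betweenness, nodes with a
#' betweenness of zero. Central and peripheral sets are kept disjoint per
#' measure (a node qualifying for both stays central).
#'
#' @param cent output of [centralities()].
#' @param frac central/peripheral fraction (default 0.30).
#' @return list with `central` and `peripheral`, each a named list over
#'   measures `degree`, `closeness`, `betweenness`.
#' @export
partition_central_peripheral <- function(cent, frac = 0.30) {
  measures <- c("degree", "closeness", "betweenness")
  central <- lapply(measures, function(m)
    top_frac_nodes(cent$node, cent[[m]], frac))
  names(central) <- measures
  n <- nrow(cent)
  k <- ceiling(frac * n)
  cc_cut <- sort(cent$closeness)[k]
  peripheral <- list(
    degree = cent$node[cent$n_neighbors <= 1L],
    closeness = cent$node[cent$closeness <= cc_cut],
    betweenness = cent$node[cent$betweenness == 0])
  peripheral <- lapply(measures, function(m)
    setdiff(peripheral[[m]], central[[m]]))
  names(peripheral) <- measures
  list(central = central, peripheral = peripheral)
}

#' Louvain community detection on the connected part of a network
#'
#' Runs the Louvain algorithm on the weighted graph restricted to connected
#' nodes, with `restarts` random vertex-order restarts keeping the
#' maximum-modularity partition. An empty edge set yields every connected
#' node (none) its own community with a warning.
#'
#' @param net a `fold_network`.
#' @param seed RNG seed for the restarts.
#' @param restarts number of restarts (default 10).
#' @return list of class `community_partition`: `membership` (named integer
#'   vector over connected nodes), `modularity`, `seed`, `class_summary`
#'   (per-community composition by node class when available).
#' @export
detect_communities <- function(net, seed = 1L, restarts = 10L) {
  check_positive_weights(net)
  g <- as_igraph(net)
  connected <- igraph::V(g)$name[igraph::degree(g) > 0]
  if (!length(connected)) {
    warning("network has no edges; every connected node is its own community")
    return(structure(list(membership = setNames(integer(0), character(0)),
                          modularity = NA_real_, seed = seed,
                          class_summary = NULL),
                     class = "community_partition"))
  }
  gs <- igraph::induced_subgraph(g, connected)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    perm <- sample(igraph::vcount(gs))
    gp <- igraph::permute(gs, perm)
    cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
    memb_p <- igraph::membership(cl)
    memb <- setNames(as.integer(memb_p[perm]), igraph::V(gs)$name)
    q <- igraph::modularity(gs, memb, weights = igraph::E(gs)$weight)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  cls_summary <- NULL
  if ("class" %in% names(net$nodes)) {
    cls <- setNames(net$nodes$class, net$nodes$node)[names(best)]
    cls_summary <- as.data.frame.matrix(table(community = best, class = cls))
  }
  structure(list(membership = best, modularity = best_q, seed = seed,
                 class_summary = cls_summary),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d nodes in %d communities, modularity %.4f\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity))
  invisible(x)
}

#' Per-network statistics panel
#'
#' Summary statistics of one network: connected-node and edge counts, the
#' number of edges not found in any sibling network at the same threshold,
#' density over connected nodes, average neighbour count, average shortest
#' path within the largest connected component (reciprocal-weight metric),
#' global clustering coefficient (closed connected triplets over all
#' connected triplets), number of components with more than one node, and
#' number with at least `large_component_min` nodes.
#'
#' @param net a `fold_network`.
#' @param siblings optional list of networks at the same threshold for the
#'   unique-edge count.
#' @param large_component_min size threshold for "large" components
#'   (default 20).
#' @return one-row data.frame.
#' @export
network_statistics <- function(net, siblings = NULL,
                               large_component_min = 20L) {
  g <- as_igraph(net)
  has_edges <- igraph::ecount(g) > 0
  connected <- igraph::V(g)$name[igraph::degree(g) > 0]
  nc <- length(connected)
  m <- igraph::ecount(g)
  uniq <- NA_integer_
  if (!is.null(siblings)) {
    mine <- pair_key(net$edges$node_a, net$edges$node_b)
    others <- unlist(lapply(siblings, function(s)
      pair_key(s$edges$node_a, s$edges$node_b)))
    uniq <- sum(!(mine %in% others))
  }
  comp <- igraph::components(g)
  real_sizes <- comp$csize[comp$csize > 1]
  avg_path <- NA_real_
  if (has_edges) {
    lcc_nodes <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    gl <- igraph::induced_subgraph(g, lcc_nodes)
    D <- igraph::distances(gl, weights = 1 / igraph::E(gl)$weight)
    avg_path <- mean(D[upper.tri(D)])
  }
  data.frame(
    method = net$method, threshold = net$threshold,
    n_connected_nodes = nc, n_edges = m, n_unique_edges = uniq,
    density = if (nc >= 2) m / choose(nc, 2) else NA_real_,
    avg_neighbors = if (nc) 2 * m / nc else NA_real_,
    avg_shortest_path_lcc = avg_path,
    clustering_coefficient = if (has_edges)
      igraph::transitivity(g, type = "global") else NA_real_,
    n_components = length(real_sizes),
    n_large_components = sum(real_sizes >= large_component_min),
    stringsAsFactors = FALSE)
}

#' Identify pivotal folds
#'
#' A fold is pivotal when it belongs to the central set under every
#' centrality measure in every network supplied (including the consensus
#' networks).
#'
#' @param partitions named list (per network) of
#'   [partition_central_peripheral()] results.
#' @return character vector of pivotal node names.
#' @export
identify_pivotal <- function(partitions) {
  sets <- unlist(lapply(partitions, function(p) p$central), recursive = FALSE)
  if (!length(sets)) return(character(0))
  Reduce(intersect, sets)
}
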