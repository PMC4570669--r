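test_that("reciprocal-weight distances match hand calculations", {
  # single edge of weight 0.5 has length 2
  n1 <- mk_net(data.frame(node_a = "a", node_b = "b", weight = 0.5))
  D <- shortest_path_matrix(n1)
  expect_equal(D["a", "b"], 2)
  # triangle: direct edge w=0.5 (length 2) loses to the two-hop w=2,2 route
  tri <- mk_net(data.frame(node_a = c("a", "a", "c"),
                           node_b = c("b", "c", "b"),
                           weight = c(0.5, 2, 2)))
  expect_equal(shortest_path_matrix(tri)["a", "b"], 1)
  # cross-component distances are infinite
  two <- mk_net(data.frame(node_a = c("a", "c"), node_b = c("b", "d"),
                           weight = 1))
  expect_equal(shortest_path_matrix(two)["a", "c"], Inf)
  # nonpositive weights refuse to run
  bad <- mk_net(data.frame(node_a = "a", node_b = "b", weight = 0))
  expect_error(shortest_path_matrix(bad), "positive")
  expect_error(centralities(bad), "positive")
})

test_that("centralities match hand examples", {
  # weighted degree is the plain sum of incident weights
  star <- mk_net(data.frame(node_a = "hub", node_b = c("l1", "l2"),
                            weight = c(0.5, 0.7)))
  cent <- centralities(star)
  expect_equal(cent$degree[cent$node == "hub"], 1.2)
  # unit-weight star: all C(4,2) = 6 leaf pairs route through the centre
  star4 <- mk_net(data.frame(node_a = "hub", node_b = paste0("l", 1:4),
                             weight = 1))
  c4 <- centralities(star4)
  expect_equal(c4$betweenness[c4$node == "hub"], 6)
  expect_true(all(c4$betweenness[c4$node != "hub"] == 0))
  # closeness of a leaf: 1/1 to hub + 3 * 1/2 to other leaves
  expect_equal(c4$closeness[c4$node == "l1"], 1 + 3 / 2)
  # isolated nodes have zero everywhere and their own component
  iso <- mk_net(data.frame(node_a = "a", node_b = "b", weight = 1),
                nodes = c("a", "b", "z"))
  ci <- centralities(iso)
  expect_equal(ci$degree[ci$node == "z"], 0)
  expect_equal(ci$closeness[ci$node == "z"], 0)
})

test_that("distances and all three centralities match brute force on random graphs", {
  set.seed(2024)
  checked <- 0
  while (checked < 12) {
    n <- sample(4:8, 1)
    ed <- random_weighted_graph(n, p = runif(1, 0.3, 0.8))
    if (nrow(ed) < 2) next
    checked <- checked + 1
    nodes <- sprintf("n%02d", seq_len(n))
    net <- mk_net(ed, nodes)
    oracle <- bf_graph_oracle(ed, nodes)
    D <- shortest_path_matrix(net)
    expect_equal(D[nodes, nodes], oracle$D, tolerance = 1e-9)
    cent <- centralities(net)
    expect_equal(setNames(cent$degree, cent$node)[nodes], oracle$degree,
                 tolerance = 1e-9)
    expect_equal(setNames(cent$closeness, cent$node)[nodes],
                 oracle$closeness, tolerance = 1e-9)
    expect_equal(setNames(cent$betweenness, cent$node)[nodes],
                 oracle$betweenness, tolerance = 1e-6)
  }
})

test_that("distance metric properties hold and rescaling behaves as expected", {
  set.seed(77)
  ed <- random_weighted_graph(7, 0.6)
  net <- mk_net(ed, sprintf("n%02d", 1:7))
  D <- shortest_path_matrix(net)
  expect_equal(D, t(D))
  fin <- is.finite(D)
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    if (fin[i, k] && fin[k, j])
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  # adding an edge never increases any distance
  ed2 <- rbind(ed, data.frame(node_a = "n01", node_b = "n07", weight = 5))
  D2 <- shortest_path_matrix(mk_net(ed2, sprintf("n%02d", 1:7)))
  expect_true(all(D2 <= D + 1e-12))
  # uniform weight rescaling: C_D and C_C scale, betweenness is invariant
  c1 <- centralities(net)
  eds <- ed; eds$weight <- 3 * eds$weight
  c3 <- centralities(mk_net(eds, sprintf("n%02d", 1:7)))
  expect_equal(c3$degree, 3 * c1$degree)
  expect_equal(c3$closeness, 3 * c1$closeness)
  expect_equal(c3$betweenness, c1$betweenness, tolerance = 1e-9)
})

test_that("central/peripheral partition implements the 30% and degenerate-node rules", {
  # 10 nodes in a path: central sets have ceiling(3) = 3 members
  ed <- data.frame(node_a = sprintf("n%02d", 1:9),
                   node_b = sprintf("n%02d", 2:10),
                   weight = seq(0.1, 0.9, by = 0.1))
  net <- mk_net(ed)
  cent <- centralities(net)
  part <- partition_central_peripheral(cent)
  expect_length(part$central$degree, 3)
  expect_length(part$central$closeness, 3)
  # path endpoints have one neighbour -> peripheral by degree,
  # and zero betweenness -> peripheral by betweenness
  expect_true(all(c("n01", "n10") %in% part$peripheral$degree))
  expect_true(all(c("n01", "n10") %in% part$peripheral$betweenness))
  # interior path nodes carry through-traffic: never betweenness-peripheral
  expect_false("n05" %in% part$peripheral$betweenness)
  # disjointness per measure
  for (m in names(part$central))
    expect_length(intersect(part$central[[m]], part$peripheral[[m]]), 0)
  # isolated node is peripheral by degree
  iso <- mk_net(ed, nodes = c(sprintf("n%02d", 1:10), "ziso"))
  parti <- partition_central_peripheral(centralities(iso))
  expect_true("ziso" %in% parti$peripheral$degree)
  # boundary ties are all included: leaves tie at the cut value, so the
  # whole star is central by degree
  tied <- mk_net(data.frame(node_a = "hub", node_b = paste0("l", 1:4),
                            weight = 1))
  pt <- partition_central_peripheral(centralities(tied))
  expect_length(pt$central$degree, 5)
})

test_that("Louvain recovers exhaustive-modularity partitions on two-clique graphs", {
  for (sizes in list(c(3, 3), c(4, 4), c(5, 5))) {
    ed <- two_clique_edges(sizes[1], sizes[2])
    nodes <- sort(unique(c(ed$node_a, ed$node_b)))
    net <- mk_net(ed, nodes)
    comm <- detect_communities(net, seed = 1, restarts = 5)
    oracle <- bf_best_partition(ed, nodes)
    # same grouping (labels may differ) and same modularity
    expect_equal(length(unique(comm$membership)), 2)
    agree <- mclust::adjustedRandIndex(comm$membership[nodes],
                                       oracle$membership[nodes])
    expect_equal(agree, 1)
    expect_equal(comm$modularity, oracle$modularity, tolerance = 1e-12)
  }
  # a single clique is one community
  clique <- two_clique_edges(5, 2)[1:10, ]  # just the first 5-clique
  cnet <- mk_net(clique)
  cc <- detect_communities(cnet, seed = 1)
  expect_equal(length(unique(cc$membership)), 1)
  # modularity never falls below the all-singletons partition
  set.seed(4)
  ed <- random_weighted_graph(8, 0.5)
  nodes <- sort(unique(c(ed$node_a, ed$node_b)))
  cm <- detect_communities(mk_net(ed, nodes), seed = 2)
  singletons <- setNames(seq_along(nodes), nodes)
  expect_gte(cm$modularity, bf_modularity(ed, nodes, singletons))
  # empty edge set warns
  expect_warning(detect_communities(mk_net(ed[0, ], nodes)), "no edges")
})

test_that("Louvain recovers the planted five-community structure on consensus networks", {
  hits <- 0
  for (s in 1:3) {
    spec <- synthetic_spec(folds_per_class = 12, domains_per_fold = 6,
                           bridge_fraction = 0.2, method_agreement = 0.98,
                           seed = 1000 + s)
    cfg <- simulate_inputs(spec, withr::local_tempdir())
    res <- run_pipeline(cfg)
    cons <- res$networks[["consensus@0.5"]]
    comm <- detect_communities(cons, seed = 1)
    truth <- attr(cfg, "truth")$communities
    planted <- setNames(truth$community, truth$fold)[names(comm$membership)]
    ari <- mclust::adjustedRandIndex(comm$membership, planted)
    if (ari >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("the statistics panel reports the documented quantities", {
  tri <- mk_net(data.frame(node_a = c("a", "a", "b"),
                           node_b = c("b", "c", "c"), weight = 1))
  st <- network_statistics(tri)
  expect_equal(st$clustering_coefficient, 1)
  expect_equal(st$n_connected_nodes, 3)
  path3 <- mk_net(data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                             weight = 1))
  expect_equal(network_statistics(path3)$clustering_coefficient, 0)
  # density over connected nodes: 4 connected nodes, 3 edges -> 0.5
  st4 <- network_statistics(mk_net(data.frame(
    node_a = c("a", "a", "a"), node_b = c("b", "c", "d"), weight = 1),
    nodes = c("a", "b", "c", "d", "iso")))
  expect_equal(st4$density, 0.5)
  expect_equal(st4$avg_neighbors, 1.5)
  expect_equal(st4$n_components, 1)
  # unique edges against sibling networks
  sib <- mk_net(data.frame(node_a = "a", node_b = "b", weight = 1))
  st5 <- network_statistics(tri, siblings = list(sib))
  expect_equal(st5$n_unique_edges, 2)
})

test_that("pivotal folds are the all-network all-measure central intersection", {
  parts <- list(
    net1 = list(central = list(degree = c("f1", "f2"),
                               closeness = c("f1", "f3"),
                               betweenness = c("f1", "f2"))),
    net2 = list(central = list(degree = c("f1", "f2"),
                               closeness = c("f1", "f2"),
                               betweenness = c("f1", "f4"))))
  expect_equal(identify_pivotal(parts), "f1")
  # one absence anywhere disqualifies
  parts$net2$central$degree <- "f2"
  expect_length(identify_pivotal(parts), 0)
})
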