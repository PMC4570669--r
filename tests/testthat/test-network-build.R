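test_that("collapse keeps the maximal-posterior alignment with provenance", {
  ann <- data.frame(
    domain_id = c("d3etja1", "d2cvea2", "dxb84a_", "dxd58a_"),
    family = c("b.84.1.1", "d.58.1.1", "b.84.1.2", "d.58.1.2"),
    superfamily = c("b.84.1", "d.58.1", "b.84.1", "d.58.1"),
    fold = c("b.84", "d.58", "b.84", "d.58"),
    class = c("b", "d", "b", "d"), stringsAsFactors = FALSE)
  post <- data.frame(
    domain_i = c("d3etja1", "dxb84a_"), domain_j = c("d2cvea2", "dxd58a_"),
    score = c(0.554, 0.30), posterior = c(0.958, 0.41),
    stringsAsFactors = FALSE)
  coll <- collapse_posteriors(post, ann, "fold")
  expect_equal(nrow(coll), 1)
  expect_equal(coll$group_a, "b.84")
  expect_equal(coll$group_b, "d.58")
  expect_equal(coll$posterior, 0.958)
  expect_equal(coll$score, 0.554)
  expect_setequal(c(coll$domain_a, coll$domain_b), c("d3etja1", "d2cvea2"))

  # missing annotation names offenders
  expect_error(collapse_posteriors(post, ann[-1, ], "fold"), "d3etja1")
})

test_that("collapse is the identity with one domain per fold and commutes with nesting", {
  spec <- synthetic_spec(folds_per_class = 3, domains_per_fold = 1, seed = 6)
  ann <- generate_hierarchy(spec)
  ps <- pair_schedule(ann$domain_id)
  set.seed(1)
  post <- data.frame(domain_i = ann$domain_id[ps$i],
                     domain_j = ann$domain_id[ps$j],
                     score = runif(ps$n_pairs),
                     posterior = runif(ps$n_pairs), stringsAsFactors = FALSE)
  coll <- collapse_posteriors(post, ann, "fold")
  expect_equal(nrow(coll), ps$n_pairs)  # every pair inter-fold, untouched
  expect_equal(sort(coll$posterior), sort(post$posterior))

  # family-then-fold max-collapse equals direct fold collapse (random tables)
  for (s in 1:3) {
    sp <- synthetic_spec(folds_per_class = 3, domains_per_fold = 4, seed = s)
    an <- generate_hierarchy(sp)
    pp <- pair_schedule(an$domain_id)
    set.seed(s + 100)
    pdf <- data.frame(domain_i = an$domain_id[pp$i],
                      domain_j = an$domain_id[pp$j],
                      score = runif(pp$n_pairs),
                      posterior = runif(pp$n_pairs), stringsAsFactors = FALSE)
    direct <- collapse_posteriors(pdf, an, "fold")
    fam <- collapse_posteriors(pdf, an, "family")
    # collapse family array to folds: treat families as pseudo-domains
    fam_ann <- unique(an[, c("family", "fold")])
    names(fam_ann) <- c("domain_id", "fold")
    fam_ann$family <- fam_ann$domain_id
    fam_ann$superfamily <- fam_ann$domain_id
    fam_ann$class <- sub("\\..*$", "", fam_ann$fold)
    fam_as_domains <- data.frame(domain_i = fam$group_a,
                                 domain_j = fam$group_b,
                                 score = fam$score, posterior = fam$posterior,
                                 stringsAsFactors = FALSE)
    via_family <- collapse_posteriors(fam_as_domains, fam_ann, "fold")
    ord <- function(d) d[order(d$group_a, d$group_b), c("group_a", "group_b", "posterior")]
    expect_equal(ord(via_family), ord(direct), ignore_attr = TRUE)
  }
})

test_that("edge weights follow each method's convention", {
  expect_equal(assign_edge_weight("tm", data.frame(tm = 0.554)), 0.554)
  expect_equal(assign_edge_weight("inverse_distance",
                                  data.frame(distance = 2.0)), 0.5)
  expect_error(assign_edge_weight("inverse_distance",
                                  data.frame(distance = 0)), "undefined")
  # zero RMSD over the full length is a perfect superposition
  expect_equal(assign_edge_weight("fatcat",
                                  data.frame(opt_rmsd = 0, len1 = 100,
                                             len2 = 100, len_aln = 100)), 1.0)
  # approximate TM decreases with RMSD, increases with length at fixed RMSD
  w1 <- fatcat_tm_approx(2, 100, 100); w2 <- fatcat_tm_approx(4, 100, 100)
  expect_gt(w1, w2)
  expect_gt(fatcat_tm_approx(3, 300, 300), fatcat_tm_approx(3, 60, 60))
  expect_error(assign_edge_weight("nope", data.frame()), "unknown")
})

test_that("static networks nest with threshold and keep the node universe", {
  spec <- tiny_spec(seed = 14)
  ann <- generate_hierarchy(spec)
  ps <- pair_schedule(ann$domain_id)
  set.seed(3)
  post <- data.frame(domain_i = ann$domain_id[ps$i],
                     domain_j = ann$domain_id[ps$j],
                     score = runif(ps$n_pairs), posterior = runif(ps$n_pairs),
                     stringsAsFactors = FALSE)
  coll <- collapse_posteriors(post, ann, "fold")
  nodes <- data.frame(node = sort(unique(ann$fold)), stringsAsFactors = FALSE)
  n5 <- build_static_network(coll, 0.5, nodes = nodes)
  n9 <- build_static_network(coll, 0.9, nodes = nodes)
  expect_true(all(n5$edges$posterior >= 0.5))
  k5 <- paste(n5$edges$node_a, n5$edges$node_b)
  k9 <- paste(n9$edges$node_a, n9$edges$node_b)
  expect_true(all(k9 %in% k5))               # 0.9 nests inside 0.5
  expect_equal(nrow(n5$nodes), length(unique(ann$fold)))  # isolates kept
  # impossible threshold empties the edge set
  expect_equal(nrow(build_static_network(coll, 1 + 1e-9, nodes = nodes)$edges), 0)
})

test_that("the static sweep emits 4 methods + consensus at 5 thresholds = 25 networks", {
  spec <- tiny_spec(seed = 2)
  cfg <- simulate_inputs(spec, withr::local_tempdir())
  res <- run_pipeline(cfg)
  expect_length(res$networks, 25)
  expect_equal(sum(grepl("^consensus@", names(res$networks))), 5)
  files <- list.files(file.path(cfg$output_dir, "networks"),
                      pattern = "_at_.*\\.graphml$")
  expect_length(files, 25)
})

test_that("consensus is the method intersection with mean-normalised weights", {
  e1 <- data.frame(node_a = c("f1", "f1"), node_b = c("f2", "f3"),
                   weight = c(0.2, 0.4), posterior = c(0.9, 0.8))
  e2 <- data.frame(node_a = c("f1", "f1"), node_b = c("f2", "f3"),
                   weight = c(2, 4), posterior = c(0.7, 0.95))
  nodes <- data.frame(node = c("f1", "f2", "f3"))
  n1 <- mk_net(e1, nodes, method = "m1"); n2 <- mk_net(e2, nodes, method = "m2")
  cons <- build_consensus(list(n1, n2))
  expect_equal(nrow(cons$edges), 2)
  ord <- order(cons$edges$node_b)
  expect_equal(cons$edges$weight[ord], c(2 / 3, 4 / 3))
  expect_true(all(cons$edges$multiplicity == 2))

  # a single shared weight normalises to exactly 1
  s1 <- mk_net(data.frame(node_a = "f1", node_b = "f2", weight = 0.5),
               nodes, method = "m1")
  s2 <- mk_net(data.frame(node_a = "f1", node_b = "f2", weight = 0.9),
               nodes, method = "m2")
  lone <- build_consensus(list(s1, s2))
  expect_equal(lone$edges$weight, 1.0)

  # an edge absent from one method is absent from the consensus
  e3 <- data.frame(node_a = "f1", node_b = "f2", weight = 1, posterior = 0.9)
  n3 <- mk_net(e3, nodes, method = "m3")
  cons3 <- build_consensus(list(n1, n2, n3))
  expect_equal(nrow(cons3$edges), 1)
  expect_equal(paste(cons3$edges$node_a, cons3$edges$node_b), "f1 f2")

  # naive independent intersection agrees on random networks
  set.seed(50)
  nets <- lapply(1:4, function(k) {
    ed <- random_weighted_graph(8, p = 0.4)
    ed$posterior <- runif(nrow(ed), 0.5, 1)
    mk_net(ed, sprintf("n%02d", 1:8), method = paste0("m", k))
  })
  if (all(vapply(nets, function(n) nrow(n$edges) > 0, TRUE))) {
    cons4 <- build_consensus(nets)
    naive <- Reduce(intersect, lapply(nets, function(n)
      paste(pmin(n$edges$node_a, n$edges$node_b),
            pmax(n$edges$node_a, n$edges$node_b))))
    expect_setequal(paste(cons4$edges$node_a, cons4$edges$node_b), naive)
  }

  # an empty contributor empties the consensus with a warning
  none <- mk_net(e1[0, ], nodes, method = "m0")
  expect_warning(c0 <- build_consensus(list(n1, none)), "zero edges")
  expect_equal(nrow(c0$edges), 0)
})

test_that("edge multiplicity partitions the pair universe", {
  nodes <- data.frame(node = sprintf("f%d", 1:5))
  mk <- function(...) mk_net(data.frame(...), nodes)
  nets <- list(
    mk(node_a = c("f1", "f2"), node_b = c("f2", "f3"), weight = 1),
    mk(node_a = c("f1", "f1"), node_b = c("f2", "f4"), weight = 1),
    mk(node_a = "f1", node_b = "f2", weight = 1),
    mk(node_a = "f1", node_b = "f2", weight = 1))
  mult <- edge_multiplicity(nets)
  pk <- paste(mult$pairs$node_a, mult$pairs$node_b)
  expect_equal(mult$pairs$multiplicity[pk == "f1 f2"], 4)
  expect_equal(mult$pairs$multiplicity[pk == "f2 f3"], 1)
  expect_equal(mult$pairs$multiplicity[pk == "f3 f4"], 0)
  expect_equal(nrow(mult$pairs), choose(5, 2))
  # histogram totals the union of edge sets
  union_size <- length(unique(unlist(lapply(nets, function(n)
    paste(n$edges$node_a, n$edges$node_b)))))
  expect_equal(sum(mult$histogram), union_size)
})

test_that("dynamic sweep assigns birth thresholds and ends at the static 0.5 frame", {
  coll <- data.frame(group_a = c("f1", "f1", "f2"),
                     group_b = c("f2", "f3", "f3"),
                     posterior = c(0.83, 0.52, 0.49),
                     score = c(0.8, 0.5, 0.4),
                     domain_a = "x", domain_b = "y", stringsAsFactors = FALSE)
  dyn <- build_dynamic_sequence(coll, grid = seq(1, 0.5, by = -0.01))
  expect_equal(dyn$edges$birth_threshold[dyn$edges$node_b == "f2"], 0.83)
  # posterior 0.49 never enters the sweep
  expect_false("f2" %in% dyn$edges$node_a)
  # edge count grows monotonically as the threshold drops
  counts <- vapply(dyn$grid, function(g) nrow(dynamic_frame(dyn, g)$edges), 0)
  expect_true(all(diff(counts) >= 0))
  # final frame equals the static network at 0.5
  fin <- dynamic_frame(dyn, 0.5)
  stat <- build_static_network(coll, 0.5, nodes = dyn$nodes)
  expect_setequal(paste(fin$edges$node_a, fin$edges$node_b),
                  paste(stat$edges$node_a, stat$edges$node_b))
  expect_error(build_dynamic_sequence(coll, grid = c(0.5, 0.6)),
               "strictly decreasing")
})

test_that("exports write readable GraphML and TSV edge lists", {
  dir <- withr::local_tempdir()
  ed <- data.frame(node_a = "f1", node_b = "f2", weight = 0.7,
                   posterior = 0.9, stringsAsFactors = FALSE)
  net <- mk_net(ed, c("f1", "f2", "f3"))
  tsv <- file.path(dir, "net.tsv"); gml <- file.path(dir, "net.graphml")
  write_edge_list(net, tsv); write_graphml(net, gml)
  back <- read.delim(tsv)
  expect_equal(back$fold_a, "f1")
  expect_equal(back$weight, 0.7)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)  # isolates survive the round trip
  expect_equal(igraph::E(g)$weight, 0.7)
})
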