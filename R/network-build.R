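# Collapse domain-level posteriors to hierarchy-level networks; static,
# dynamic and consensus network construction.

#' Attach alignment posteriors to a score table
#'
#' Computes every pair's posterior probability of fold co-membership using
#' the partition-appropriate calibration model: pairs where either domain
#' belongs to the all-alpha class use the `alpha_involved` model when the
#' calibration was partitioned.
#'
#' @param tab a [score_table()].
#' @param calset a `calibration_set` from [fit_calibration()].
#' @param annotation domain annotation table (`domain_id`, `class`, ...).
#' @param score_col score column to use (default `"score"`).
#' @return data.frame `domain_i`, `domain_j`, `score`, `posterior`.
#' @export
score_posteriors <- function(tab, calset, annotation, score_col = "score") {
  stopifnot(inherits(tab, "score_table"), inherits(calset, "calibration_set"))
  cls <- setNames(annotation$class, annotation$domain_id)
  missing <- setdiff(unique(c(tab$domain_i, tab$domain_j)), names(cls))
  if (length(missing))
    stop("domains missing annotation: ", paste(missing, collapse = ", "))
  s <- tab[[score_col]]
  post <- numeric(nrow(tab))
  if (!is.null(calset$models$all)) {
    post <- as.numeric(posterior_of_alignment(calset$models$all, s))
  } else {
    alpha <- cls[tab$domain_i] == "a" | cls[tab$domain_j] == "a"
    if (any(alpha))
      post[alpha] <- as.numeric(
        posterior_of_alignment(calset$models$alpha_involved, s[alpha]))
    if (any(!alpha))
      post[!alpha] <- as.numeric(
        posterior_of_alignment(calset$models$other, s[!alpha]))
  }
  data.frame(domain_i = tab$domain_i, domain_j = tab$domain_j,
             score = s, posterior = post, stringsAsFactors = FALSE)
}

#' Collapse domain-pair posteriors to a hierarchy level
#'
#' Entry (A, B) of the group-level array carries the single cross-group
#' alignment with the maximal posterior probability, together with its
#' provenance (the best domain pair and its raw score). Intra-group pairs
#' are dropped.
#'
#' @param post_df output of [score_posteriors()].
#' @param annotation domain annotation table.
#' @param level `"family"`, `"superfamily"` or `"fold"`.
#' @return data.frame `group_a`, `group_b`, `posterior`, `score`,
#'   `domain_a`, `domain_b` (one row per group pair).
#' @export
collapse_posteriors <- function(post_df, annotation,
                                level = c("fold", "family", "superfamily")) {
  level <- match.arg(level)
  grp <- setNames(annotation[[level]], annotation$domain_id)
  missing <- setdiff(unique(c(post_df$domain_i, post_df$domain_j)), names(grp))
  if (length(missing))
    stop("domains missing annotation: ", paste(missing, collapse = ", "))
  ga <- grp[post_df$domain_i]; gb <- grp[post_df$domain_j]
  inter <- ga != gb
  a <- pmin(ga[inter], gb[inter]); b <- pmax(ga[inter], gb[inter])
  d <- data.frame(group_a = a, group_b = b,
                  posterior = post_df$posterior[inter],
                  score = post_df$score[inter],
                  domain_a = post_df$domain_i[inter],
                  domain_b = post_df$domain_j[inter],
                  stringsAsFactors = FALSE)
  # max posterior per group pair; ties resolved towards the higher raw score
  o <- order(d$group_a, d$group_b, -d$posterior, -d$score)
  d <- d[o, , drop = FALSE]
  keep <- !duplicated(paste(d$group_a, d$group_b))
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Approximate TM-score from an RMSD and domain lengths
#'
#' The TM functional with every aligned deviation set to the reported RMSD:
#' \eqn{TM = (L_{aln}/\bar L)\cdot 1/(1+(rmsd/d_0(\bar L))^2)} with the
#' canonical \eqn{d_0(L) = 1.24 (L-15)^{1/3} - 1.8} and \eqn{\bar L} the mean
#' of the two domain lengths. Used to weight edges for methods (FATCAT-like)
#' that report an optimal RMSD but no TM-score; flagged as approximate in
#' provenance.
#'
#' @param opt_rmsd optimal superposition RMSD in angstrom.
#' @param len1,len2 domain lengths in residues.
#' @param len_aln aligned length; defaults to the mean domain length
#'   (full-length alignment).
#' @return approximate TM-score in (0, 1\].
#' @export
fatcat_tm_approx <- function(opt_rmsd, len1, len2, len_aln = NULL) {
  stopifnot(all(opt_rmsd >= 0), all(len1 > 0), all(len2 > 0))
  lbar <- (len1 + len2) / 2
  if (is.null(len_aln)) len_aln <- lbar
  d0 <- pmax(0.5, 1.24 * (lbar - 15)^(1 / 3) - 1.8)
  (len_aln / lbar) / (1 + (opt_rmsd / d0)^2)
}

#' Assign an edge weight from an alignment record
#'
#' Weight conventions per method: TM-score-reporting methods use the
#' TM-score itself (`"tm"` reads column `tm`, `"score"` the generic score
#' column); `"fatcat"` derives an approximate TM-score from `opt_rmsd`,
#' `len1`, `len2` via [fatcat_tm_approx()]; `"inverse_distance"` uses the
#' reciprocal of a distance score (elastic-metric style), which requires a
#' strictly positive distance. All weights are positive with greater =
#' more similar.
#'
#' @param rule one of `"tm"`, `"score"`, `"fatcat"`, `"inverse_distance"`.
#' @param record data.frame (or row) with the fields the rule needs.
#' @return numeric weights.
#' @export
assign_edge_weight <- function(rule, record) {
  switch(rule,
    tm = record$tm,
    score = record$score,
    fatcat = fatcat_tm_approx(record$opt_rmsd, record$len1, record$len2,
                              record$len_aln),
    inverse_distance = {
      d <- if (!is.null(record$distance)) record$distance else record$score
      if (any(d <= 0)) stop("inverse of a non-positive elastic metric is undefined")
      1 / d
    },
    stop("unknown weight rule: ", rule))
}

# node table for a fold-level universe: class, size, optional age
fold_node_table <- function(annotation, ages = NULL,
                            level = "fold") {
  grp <- annotation[[level]]
  nodes <- data.frame(node = sort(unique(grp)), stringsAsFactors = FALSE)
  nodes$class <- sub("\\..*$", "", nodes$node)
  nodes$size <- as.integer(table(grp)[nodes$node])
  if (!is.null(ages)) nodes$age <- ages$age[match(nodes$node, ages$fold)]
  nodes
}

#' Build a static fold network at one posterior threshold
#'
#' Edges are the collapsed group pairs whose posterior is at least the
#' threshold (closed comparison). The node universe retains unconnected
#' groups; renderers may drop them but analyses keep them.
#'
#' @param collapsed output of [collapse_posteriors()] with a `weight` column
#'   (see [assign_edge_weight()]), or without one, in which case the raw
#'   score is used as the weight.
#' @param threshold posterior threshold in (0, 1\].
#' @param nodes node table (`node`, plus attributes); defaults to the groups
#'   appearing in `collapsed`.
#' @param method,level metadata strings.
#' @return object of class `fold_network`: list with `method`, `level`,
#'   `threshold`, `nodes`, `edges`.
#' @export
build_static_network <- function(collapsed, threshold, nodes = NULL,
                                 method = "method", level = "fold") {
  stopifnot(threshold > 0)
  if (is.null(collapsed$weight)) collapsed$weight <- collapsed$score
  if (is.null(nodes))
    nodes <- data.frame(node = sort(unique(c(collapsed$group_a,
                                             collapsed$group_b))),
                        stringsAsFactors = FALSE)
  keep <- !is.na(collapsed$posterior) & collapsed$posterior >= threshold
  edges <- collapsed[keep, , drop = FALSE]
  names(edges)[names(edges) == "group_a"] <- "node_a"
  names(edges)[names(edges) == "group_b"] <- "node_b"
  rownames(edges) <- NULL
  structure(list(method = method, level = level, threshold = threshold,
                 nodes = nodes, edges = edges),
            class = "fold_network")
}

#' @export
print.fold_network <- function(x, ...) {
  cat(sprintf("fold_network: %s @ %s level, threshold %.3g: %d nodes (%d connected), %d edges\n",
              x$method, x$level, x$threshold, nrow(x$nodes),
              length(unique(c(x$edges$node_a, x$edges$node_b))),
              nrow(x$edges)))
  invisible(x)
}

#' Convert a fold network to an igraph graph
#'
#' Undirected, with the full node universe as vertices (isolates retained)
#' and edge attributes `weight` and `posterior`.
#'
#' @param net a `fold_network` or `consensus_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, c("fold_network", "consensus_network")))
  ecols <- intersect(c("node_a", "node_b", "weight", "posterior",
                       "multiplicity"), names(net$edges))
  igraph::graph_from_data_frame(net$edges[, ecols, drop = FALSE],
                                directed = FALSE, vertices = net$nodes)
}

#' Annotate edges with their birth threshold along a dynamic sweep
#'
#' As the posterior threshold decreases from 1 towards 0.5, each collapsed
#' pair first appears at the highest grid value not exceeding its posterior.
#' Pairs whose posterior falls below the lowest grid value never appear.
#'
#' @param collapsed output of [collapse_posteriors()] (optionally weighted).
#' @param grid strictly decreasing threshold grid, e.g.
#'   `seq(1, 0.5, by = -0.01)`.
#' @param nodes,method,level as in [build_static_network()].
#' @return object of class `dynamic_sequence`: list with `grid`, `edges`
#'   (with `birth_threshold`), `nodes`, `method`, `level`. Use
#'   [dynamic_frame()] to materialise a single frame.
#' @export
build_dynamic_sequence <- function(collapsed, grid = seq(1, 0.5, by = -0.01),
                                   nodes = NULL, method = "method",
                                   level = "fold") {
  if (any(diff(grid) >= 0)) stop("threshold grid must be strictly decreasing")
  if (is.null(collapsed$weight)) collapsed$weight <- collapsed$score
  asc <- sort(grid)
  idx <- findInterval(collapsed$posterior, asc)     # highest grid value <= posterior
  birth <- ifelse(idx == 0, NA_real_, asc[pmax(idx, 1L)])
  edges <- collapsed[!is.na(birth), , drop = FALSE]
  edges$birth_threshold <- birth[!is.na(birth)]
  names(edges)[names(edges) == "group_a"] <- "node_a"
  names(edges)[names(edges) == "group_b"] <- "node_b"
  rownames(edges) <- NULL
  if (is.null(nodes))
    nodes <- data.frame(node = sort(unique(c(collapsed$group_a,
                                             collapsed$group_b))),
                        stringsAsFactors = FALSE)
  structure(list(grid = grid, edges = edges, nodes = nodes, method = method,
                 level = level),
            class = "dynamic_sequence")
}

#' Materialise one frame of a dynamic sequence
#'
#' @param dyn a `dynamic_sequence`.
#' @param threshold a grid value.
#' @return a `fold_network` holding the edges born at or above `threshold`.
#' @export
dynamic_frame <- function(dyn, threshold) {
  stopifnot(inherits(dyn, "dynamic_sequence"))
  edges <- dyn$edges[dyn$edges$birth_threshold >= threshold, , drop = FALSE]
  edges$birth_threshold <- NULL
  rownames(edges) <- NULL
  structure(list(method = dyn$method, level = dyn$level, threshold = threshold,
                 nodes = dyn$nodes, edges = edges),
            class = "fold_network")
}

#' Build the consensus network over methods at one threshold
#'
#' Consensus edges are the fold pairs present in every contributing
#' method's network at the same threshold and level. Each method's edge
#' weights are first centred by dividing by that method's mean edge weight
#' over its own network at this threshold; the consensus weight is the mean
#' of the centred weights.
#'
#' @param nets named list of `fold_network`s (one per method) sharing level
#'   and threshold.
#' @return object of class `consensus_network` (also a `fold_network`):
#'   edges carry `weight` (mean-normalised) and `multiplicity` (= number of
#'   methods, by construction).
#' @export
build_consensus <- function(nets) {
  stopifnot(length(nets) >= 2, all(vapply(nets, inherits, TRUE, "fold_network")))
  thr <- unique(vapply(nets, `[[`, 0, "threshold"))
  lev <- unique(vapply(nets, `[[`, "", "level"))
  if (length(thr) != 1L || length(lev) != 1L)
    stop("consensus requires networks at a shared level and threshold")
  if (any(vapply(nets, function(n) nrow(n$edges) == 0L, TRUE)))
    warning("a contributing method has zero edges; consensus is empty")
  keys <- lapply(nets, function(n) pair_key(n$edges$node_a, n$edges$node_b))
  common <- Reduce(intersect, keys)
  norm_w <- lapply(seq_along(nets), function(k) {
    e <- nets[[k]]$edges
    w <- e$weight / mean(e$weight)
    setNames(w, keys[[k]])
  })
  if (length(common)) {
    wmat <- vapply(norm_w, function(w) w[common], numeric(length(common)))
    if (is.null(dim(wmat))) wmat <- matrix(wmat, nrow = length(common))
    weight <- rowMeans(wmat)
    ab <- do.call(rbind, strsplit(common, "|", fixed = TRUE))
    edges <- data.frame(node_a = ab[, 1], node_b = ab[, 2],
                        weight = weight,
                        multiplicity = length(nets),
                        stringsAsFactors = FALSE)
    # minimum posterior across methods, for reference
    post <- vapply(seq_along(nets), function(k) {
      e <- nets[[k]]$edges
      setNames(e$posterior, keys[[k]])[common]
    }, numeric(length(common)))
    if (is.null(dim(post))) post <- matrix(post, nrow = length(common))
    edges$posterior <- apply(post, 1, min)
  } else {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        weight = numeric(0), multiplicity = integer(0),
                        posterior = numeric(0), stringsAsFactors = FALSE)
  }
  nodes <- nets[[1]]$nodes
  structure(list(method = "consensus", level = lev, threshold = thr,
                 nodes = nodes, edges = edges,
                 methods = vapply(nets, `[[`, "", "method")),
            class = c("consensus_network", "fold_network"))
}

#' Static network sweep: per-method and consensus networks
#'
#' Builds, for every threshold, one network per method plus their consensus
#' (with four methods and the default five thresholds: 25 static networks).
#'
#' @param collapsed_list named list (per method) of weighted collapsed
#'   arrays.
#' @param thresholds posterior thresholds (default 0.5-0.9).
#' @param nodes shared node universe table.
#' @param level hierarchy level string.
#' @return named list of networks, keys `<method>@<threshold>` and
#'   `consensus@<threshold>`.
#' @export
build_network_sweep <- function(collapsed_list,
                                thresholds = seq(0.5, 0.9, by = 0.1),
                                nodes = NULL, level = "fold") {
  out <- list()
  for (thr in thresholds) {
    per_method <- lapply(names(collapsed_list), function(m)
      build_static_network(collapsed_list[[m]], thr, nodes = nodes,
                           method = m, level = level))
    names(per_method) <- names(collapsed_list)
    for (m in names(per_method))
      out[[sprintf("%s@%s", m, format(thr))]] <- per_method[[m]]
    out[[sprintf("consensus@%s", format(thr))]] <-
      suppressWarnings(build_consensus(per_method))
  }
  out
}

#' Edge multiplicity over the method networks at one threshold
#'
#' Assigns every fold pair of the node universe the number of methods whose
#' network at this threshold displays it as an edge (0 = unconnected pair),
#' and reports the histogram over multiplicities 1 to the number of methods.
#'
#' @param nets list of per-method `fold_network`s sharing the node universe.
#' @param nodes optional node table; defaults to the first network's.
#' @return list with `pairs` (data.frame `node_a`, `node_b`,
#'   `multiplicity`) and `histogram` (named counts over 1..n_methods).
#' @export
edge_multiplicity <- function(nets, nodes = NULL) {
  stopifnot(length(nets) >= 1)
  if (is.null(nodes)) nodes <- nets[[1]]$nodes
  ids <- sort(nodes$node)
  ps <- pair_schedule(length(ids))
  keys <- pair_key(ids[ps$i], ids[ps$j])
  count <- setNames(integer(length(keys)), keys)
  for (n in nets) {
    k <- pair_key(n$edges$node_a, n$edges$node_b)
    count[k] <- count[k] + 1L
  }
  hist <- vapply(seq_along(nets), function(m) sum(count == m), integer(1))
  names(hist) <- seq_along(nets)
  list(pairs = data.frame(node_a = ids[ps$i], node_b = ids[ps$j],
                          multiplicity = unname(count),
                          stringsAsFactors = FALSE),
       histogram = hist)
}

#' Write a fold network as a weighted edge-list TSV
#'
#' Columns: fold_a, fold_b, posterior, weight, plus multiplicity and
#' provenance columns where present.
#'
#' @param net a `fold_network`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_edge_list <- function(net, file) {
  e <- net$edges
  cols <- intersect(c("node_a", "node_b", "posterior", "weight",
                      "multiplicity", "domain_a", "domain_b", "score",
                      "birth_threshold"), names(e))
  out <- e[, cols, drop = FALSE]
  names(out)[1:2] <- c("fold_a", "fold_b")
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a network (or dynamic sequence) as GraphML
#'
#' @param net a `fold_network`, `consensus_network` or `dynamic_sequence`
#'   (the latter exports per-edge `birth_threshold` for animation tooling).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_graphml <- function(net, file) {
  g <- if (inherits(net, "dynamic_sequence")) {
    ecols <- intersect(c("node_a", "node_b", "weight", "posterior",
                         "birth_threshold"), names(net$edges))
    igraph::graph_from_data_frame(net$edges[, ecols, drop = FALSE],
                                  directed = FALSE, vertices = net$nodes)
  } else as_igraph(net)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
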