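# Independent brute-force oracles used to check the graph machinery, plus
# small fixture builders. Everything here is deliberately naive and
# independent of the package's implementation paths.

# build a fold_network directly from an edge data.frame
mk_net <- function(edges, nodes = NULL, threshold = 0.5, method = "m") {
  if (is.null(edges$posterior)) edges$posterior <- rep(threshold, nrow(edges))
  if (is.null(nodes)) {
    nodes <- data.frame(node = sort(unique(c(edges$node_a, edges$node_b))),
                        stringsAsFactors = FALSE)
  } else if (!is.data.frame(nodes)) {
    nodes <- data.frame(node = nodes, stringsAsFactors = FALSE)
  }
  structure(list(method = method, level = "fold", threshold = threshold,
                 nodes = nodes, edges = edges),
            class = "fold_network")
}

# random connected-ish weighted graph on n nodes
random_weighted_graph <- function(n, p = 0.5) {
  nodes <- sprintf("n%02d", seq_len(n))
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) { ea <- c(ea, nodes[i]); eb <- c(eb, nodes[j]) }
  }
  data.frame(node_a = ea, node_b = eb,
             weight = runif(length(ea), 0.2, 2),
             stringsAsFactors = FALSE)
}

# --- exhaustive path oracle -------------------------------------------------
# all simple paths between two nodes, via DFS on an adjacency list
all_simple_paths_bf <- function(adj, from, to) {
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) { paths[[length(paths) + 1L]] <<- path; return() }
    for (nxt in adj[[last]]) if (!(nxt %in% path)) walk(c(path, nxt))
  }
  walk(from)
  paths
}

# brute-force distances, path counts and centralities under the
# reciprocal-weight metric; near-equal path lengths treated as equal within
# relative tolerance 1e-9
bf_graph_oracle <- function(edges, nodes) {
  n <- length(nodes)
  wmap <- new.env()
  adj <- setNames(vector("list", n), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$node_a[r]; b <- edges$node_b[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    assign(paste(a, b), edges$weight[r], envir = wmap)
    assign(paste(b, a), edges$weight[r], envir = wmap)
  }
  plen <- function(path) {
    if (length(path) < 2) return(0)
    sum(vapply(seq_len(length(path) - 1L), function(k)
      1 / get(paste(path[k], path[k + 1]), envir = wmap), 0))
  }
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes)); diag(D) <- 0
  npaths <- matrix(0, n, n, dimnames = list(nodes, nodes))
  through <- array(0, c(n, n, n), dimnames = list(nodes, nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- all_simple_paths_bf(adj, nodes[i], nodes[j])
    if (!length(ps)) next
    lens <- vapply(ps, plen, 0)
    dmin <- min(lens)
    sel <- lens <= dmin * (1 + 1e-9)
    D[i, j] <- D[j, i] <- dmin
    npaths[i, j] <- npaths[j, i] <- sum(sel)
    for (p in ps[sel]) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      for (v in inner) through[i, j, v] <- through[j, i, v] <-
          through[i, j, v] + 1
    }
  }
  deg <- setNames(numeric(n), nodes)
  for (r in seq_len(nrow(edges))) {
    deg[edges$node_a[r]] <- deg[edges$node_a[r]] + edges$weight[r]
    deg[edges$node_b[r]] <- deg[edges$node_b[r]] + edges$weight[r]
  }
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]; sum(1 / d[is.finite(d)])
  }, 0)
  cb <- vapply(nodes, function(v) {
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (nodes[i] == v || nodes[j] == v || npaths[i, j] == 0) next
      tot <- tot + through[i, j, v] / npaths[i, j]
    }
    tot
  }, 0)
  list(D = D, degree = deg, closeness = setNames(cc, nodes),
       betweenness = cb)
}

# --- exhaustive modularity oracle -------------------------------------------
# all set partitions of n items as restricted growth strings (one per column)
all_partitions <- function(n) {
  bell <- c(1, 1, 2, 5, 15, 52, 203, 877, 4140, 21147, 115975)
  out <- matrix(0L, n, bell[n + 1])
  k <- 0L
  rec <- function(prefix, maxb) {
    if (length(prefix) == n) {
      k <<- k + 1L
      out[, k] <<- prefix
      return()
    }
    for (b in seq_len(maxb + 1L)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  out
}

# Newman weighted modularity of a membership vector, computed from scratch
bf_modularity <- function(edges, nodes, memb) {
  m2 <- 2 * sum(edges$weight)
  deg <- setNames(numeric(length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    deg[edges$node_a[r]] <- deg[edges$node_a[r]] + edges$weight[r]
    deg[edges$node_b[r]] <- deg[edges$node_b[r]] + edges$weight[r]
  }
  within <- sum(edges$weight[memb[edges$node_a] == memb[edges$node_b]])
  sum_dc2 <- sum(tapply(deg, memb[nodes], sum)^2)
  2 * within / m2 - sum_dc2 / m2^2
}

# exhaustive maximum-modularity partition by enumerating every set partition
bf_best_partition <- function(edges, nodes) {
  n <- length(nodes)
  parts <- all_partitions(n)
  ia <- match(edges$node_a, nodes); ib <- match(edges$node_b, nodes)
  w <- edges$weight
  m2 <- 2 * sum(w)
  deg <- numeric(n)
  for (r in seq_along(w)) {
    deg[ia[r]] <- deg[ia[r]] + w[r]; deg[ib[r]] <- deg[ib[r]] + w[r]
  }
  best_q <- -Inf; best_k <- 0L
  for (k in seq_len(ncol(parts))) {
    p <- parts[, k]
    within <- sum(w[p[ia] == p[ib]])
    q <- 2 * within / m2 - sum(rowsum(deg, p)^2) / m2^2
    if (q > best_q) { best_q <- q; best_k <- k }
  }
  list(membership = setNames(parts[, best_k], nodes), modularity = best_q)
}

# --- naive rank statistics ---------------------------------------------------
# Mann-Whitney U by direct pair counting (ties count half)
bf_mann_whitney_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# AUROC by concordant-pair counting
bf_auroc <- function(scores, sibling) {
  s <- scores[sibling]; u <- scores[!sibling]
  bf_mann_whitney_u(s, u) / (length(s) * length(u))
}

# naive two-clique graph: two cliques of sizes n1, n2 joined by one edge
two_clique_edges <- function(n1, n2, w = 1) {
  nodes <- c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2)))
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n1 - 1)) for (j in (i + 1):n1) {
    ea <- c(ea, nodes[i]); eb <- c(eb, nodes[j])
  }
  for (i in seq_len(n2 - 1)) for (j in (i + 1):n2) {
    ea <- c(ea, nodes[n1 + i]); eb <- c(eb, nodes[n1 + j])
  }
  ea <- c(ea, nodes[1]); eb <- c(eb, nodes[n1 + 1])
  data.frame(node_a = ea, node_b = eb, weight = w, stringsAsFactors = FALSE)
}

# tiny default spec for fast pipeline tests
tiny_spec <- function(seed = 1, ...) {
  synthetic_spec(folds_per_class = 4, domains_per_fold = 2, seed = seed, ...)
}
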