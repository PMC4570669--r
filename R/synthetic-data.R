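#' Generate a SCOP-like domain annotation table
#'
#' Builds the planted hierarchy: classes labelled `a`, `b`, ... contain
#' folds (`"b.3"`), each fold contains superfamilies (`"b.3.1"`), families
#' (`"b.3.1.2"`) and domains. Domains are distributed over roughly
#' `ceiling(n/2)` families per fold (two superfamilies once a fold has more
#' than one family) so the family/superfamily collapse steps are
#' non-trivial.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `domain_id`, `family`, `superfamily`,
#'   `fold`, `class`.
#' @export
generate_hierarchy <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(child_seed(spec, "hierarchy"))
  classes <- letters[seq_len(spec$n_classes)]
  rows <- list()
  for (cl in classes) {
    for (f in seq_len(spec$folds_per_class)) {
      fold <- paste0(cl, ".", f)
      nd <- if (length(spec$domains_per_fold) == 2L)
        sample(spec$domains_per_fold[1]:spec$domains_per_fold[2], 1L)
      else spec$domains_per_fold
      n_fam <- max(1L, ceiling(nd / 2))
      fam_of <- rep_len(seq_len(n_fam), nd)
      n_sf <- max(1L, ceiling(n_fam / 2))
      sf_of_fam <- rep_len(seq_len(n_sf), n_fam)
      rows[[length(rows) + 1L]] <- data.frame(
        domain_id = sprintf("dom_%s_%02d", fold, seq_len(nd)),
        family = sprintf("%s.%d.%d", fold, sf_of_fam[fam_of], fam_of),
        superfamily = sprintf("%s.%d", fold, sf_of_fam[fam_of]),
        fold = fold, class = cl, stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  ann
}

#' Planted community of each fold
#'
#' The default five-community plan over four classes: class `a` is one
#' community (all-alpha), `c` one (alpha/beta), `d` one (alpha+beta), and
#' class `b` is split in two equal halves (beta-sandwich / beta-barrel).
#' With other class counts each class is its own community.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `fold`, `community`.
#' @export
planted_communities <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- letters[seq_len(spec$n_classes)]
  out <- list()
  for (cl in classes) {
    folds <- paste0(cl, ".", seq_len(spec$folds_per_class))
    if (cl == "b" && spec$n_classes >= 4 && spec$folds_per_class >= 2) {
      half <- ceiling(length(folds) / 2)
      comm <- c(rep("beta_sandwich", half),
                rep("beta_barrel", length(folds) - half))
    } else {
      comm <- rep(switch(cl, a = "all_alpha", c = "alpha_beta",
                         d = "alpha_plus_beta", paste0("class_", cl)),
                  length(folds))
    }
    out[[cl]] <- data.frame(fold = folds, community = comm,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant inter-fold bridges
#'
#' `bridge_fraction` of all unordered inter-fold pairs are planted as
#' bridges. Each planted bridge is allocated to a same-community fold pair
#' with probability `intra_community_affinity` (default 0.9) and to a
#' cross-community pair otherwise, drawing pairs without replacement from
#' the respective pools (spilling over to the other pool if one runs out).
#' This concentrates bridges inside the five planted communities, the block
#' structure community detection is meant to recover.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame `fold_a`, `fold_b`, `same_community`.
#' @export
plant_bridges <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  comm <- planted_communities(spec)
  set.seed(child_seed(spec, "bridges"))
  ps <- pair_schedule(nrow(comm))
  i <- ps$i; j <- ps$j
  same <- comm$community[i] == comm$community[j]
  n_bridges <- round(spec$bridge_fraction * length(i))
  w_in <- spec$intra_community_affinity
  w_cross <- spec$cross_community_affinity
  p_in <- if (w_in + w_cross > 0) w_in / (w_in + w_cross) else 0
  n_in <- min(rbinom(1, n_bridges, p_in), sum(same))
  n_out <- min(n_bridges - n_in, sum(!same))
  n_in <- min(n_in + (n_bridges - n_in - n_out), sum(same))  # spill-over
  keep <- c(sample(which(same), n_in), sample(which(!same), n_out))
  keep <- sort(keep)
  data.frame(fold_a = comm$fold[i][keep], fold_b = comm$fold[j][keep],
             same_community = same[keep], stringsAsFactors = FALSE)
}

#' Generate one score table per pseudo-method
#'
#' All unordered domain pairs are scored by every method. Fold siblings draw
#' from the method's sibling distribution and unrelated pairs from its
#' unrelated distribution, except that each planted bridge designates one
#' representative cross-fold domain pair which, independently per method
#' with probability `method_agreement`, draws from the sibling distribution
#' instead (a "visible" bridge). Every method additionally emits an
#' uninformative `aux` column so score selection by AUROC has something to
#' reject.
#'
#' @param spec a [synthetic_spec()].
#' @param annotation table from [generate_hierarchy()].
#' @param bridges planted bridges, default [plant_bridges()].
#' @return named list of [score_table()] objects, one per method, with
#'   attributes `bridges` (fold pairs plus per-method visibility flags and
#'   the representative domain pair) and `spec`.
#' @export
generate_score_tables <- function(spec, annotation, bridges = plant_bridges(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  force(bridges)  # plant_bridges seeds its own RNG stream; evaluate it
                  # before this stage's seed is set

  exp_folds <- spec$n_classes * spec$folds_per_class
  if (!all(c("domain_id", "fold") %in% names(annotation)) ||
      length(unique(annotation$fold)) != exp_folds)
    stop("annotation/spec mismatch: fold inventory does not match the spec")
  set.seed(child_seed(spec, "scores"))
  ids <- annotation$domain_id
  fold <- setNames(annotation$fold, ids)
  ps <- pair_schedule(length(ids))
  di <- ids[ps$i]; dj <- ids[ps$j]
  sib <- fold[di] == fold[dj]
  fold_pair <- pair_key(fold[di], fold[dj])

  # one representative domain pair per planted bridge
  np <- length(di)
  bridge_pair_idx <- integer(0)
  if (nrow(bridges)) {
    bkey <- pair_key(bridges$fold_a, bridges$fold_b)
    bridge_pair_idx <- vapply(bkey, function(k) {
      cand <- which(fold_pair == k)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1))
    bridges$domain_a <- di[bridge_pair_idx]
    bridges$domain_b <- dj[bridge_pair_idx]
  }

  tabs <- list()
  for (m in spec$methods) {
    score <- numeric(np)
    score[sib] <- rtruncnorm(sum(sib), m$sibling[1], m$sibling[2])
    score[!sib] <- rtruncnorm(sum(!sib), m$unrelated[1], m$unrelated[2])
    vis <- logical(nrow(bridges))
    if (length(bridge_pair_idx)) {
      vis <- runif(length(bridge_pair_idx)) < spec$method_agreement
      idx <- bridge_pair_idx[vis]
      score[idx] <- rtruncnorm(length(idx), m$sibling[1], m$sibling[2])
    }
    bridges[[paste0("visible_", m$name)]] <- vis
    aux <- rtruncnorm(np, 0.5, 0.15)  # carries no fold signal
    tabs[[m$name]] <- score_table(
      data.frame(domain_i = di, domain_j = dj, score = score, aux = aux,
                 stringsAsFactors = FALSE),
      method = m$name, orientation = m$orientation)
  }
  attr(tabs, "bridges") <- bridges
  attr(tabs, "spec") <- spec
  tabs
}

#' Generate a fold-age table with planted bridge assortativity
#'
#' Ages are uniform on \[0, 1\] subject to the planted constraint that
#' bridge endpoints differ by at most `age_assortativity` (the law of
#' resampling until every bridge satisfies the bound). Realised by a
#' breadth-first pass over each connected component of the bridge graph
#' (each fold drawn uniformly on the window around its tree parent)
#' followed by repair sweeps that redraw one endpoint of any still-violating
#' bridge inside its partner's window. With `age_assortativity = 0`
#' constrained endpoints share one age draw; with `age_assortativity >= 1`
#' the constraint is vacuous and ages are plain uniforms. Bridges still
#' violating after the repair budget are counted in the attached log.
#'
#' @param spec a [synthetic_spec()].
#' @param annotation table from [generate_hierarchy()].
#' @param bridges planted bridges (fold pairs).
#' @param max_sweeps repair sweep budget.
#' @return data.frame `fold`, `age` with attribute `log`.
#' @export
generate_ages <- function(spec, annotation, bridges = plant_bridges(spec),
                          max_sweeps = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  force(bridges)  # evaluate the default (which seeds its own stream) first
  folds <- unique(annotation$fold)
  set.seed(child_seed(spec, "ages"))
  age <- setNames(runif(length(folds)), folds)
  delta <- spec$age_assortativity
  n_violating <- 0L
  if (nrow(bridges) && delta < 1) {
    keep <- bridges$fold_a %in% folds & bridges$fold_b %in% folds
    bb <- bridges[keep, c("fold_a", "fold_b"), drop = FALSE]
    if (nrow(bb)) {
      g <- igraph::graph_from_data_frame(bb, directed = FALSE,
                                         vertices = folds)
      draw_near <- function(a) {
        if (delta == 0) return(a)
        runif(1, max(0, a - delta), min(1, a + delta))
      }
      comp <- igraph::components(g)$membership
      for (cid in unique(comp)) {
        members <- names(comp)[comp == cid]
        if (length(members) == 1L) next
        ord <- igraph::bfs(g, root = members[1], unreachable = FALSE)$order
        ord <- igraph::V(g)$name[ord[!is.na(ord)]]
        parent <- character(0)
        for (v in ord[-1]) {
          nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
          anchor <- intersect(ord[seq_len(match(v, ord) - 1L)], nb)[1]
          age[v] <- draw_near(age[anchor])
        }
      }
      # repair: redraw one endpoint of a violating bridge inside the
      # intersection of ALL its partners' windows, so already-satisfied
      # constraints stay satisfied (no cascading collapse)
      nbrs <- lapply(setNames(folds, folds), function(v)
        igraph::V(g)$name[igraph::neighbors(g, v)])
      try_redraw <- function(v) {
        w <- nbrs[[v]]
        lo <- max(0, max(age[w] - delta)); hi <- min(1, min(age[w] + delta))
        if (lo > hi) return(FALSE)
        age[v] <<- if (delta == 0) lo else runif(1, lo, hi)
        TRUE
      }
      viol <- function() which(abs(age[bb$fold_a] - age[bb$fold_b]) > delta)
      for (sweep in seq_len(max_sweeps)) {
        v <- viol()
        if (!length(v)) break
        for (r in v) {
          if (abs(age[bb$fold_a[r]] - age[bb$fold_b[r]]) <= delta) next
          if (!try_redraw(bb$fold_b[r])) try_redraw(bb$fold_a[r])
        }
      }
      n_violating <- length(viol())
    }
  }
  out <- data.frame(fold = folds, age = unname(age[folds]),
                    stringsAsFactors = FALSE)
  attr(out, "log") <- list(n_bridges = nrow(bridges),
                           n_unresolved = n_violating)
  out
}

#' Write minimal PDB coordinate fixtures
#'
#' Emits one single-chain PDB file per synthetic domain: poly-alanine traces
#' with consecutive C-alpha atoms 3.8 angstrom apart, a stated fraction with
#' one planted gap larger than the 4.3 angstrom chain-break threshold, and a
#' stated fraction reduced to C-alpha-only records. These files are
#' synthetic stand-ins for real domain structures and exist solely to
#' exercise the coordinate QC stage.
#'
#' @param n_domains number of files.
#' @param break_fraction fraction of files with one planted >4.3 A gap.
#' @param calpha_only_fraction fraction of files stripped to C-alpha atoms.
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param n_res residues per chain.
#' @param gap_size planted gap size in angstrom (default 6.0).
#' @return data.frame manifest: `file`, `calpha_only`, `break_after`
#'   (residue index before the planted gap, `NA` if none).
#' @export
generate_coordinate_fixtures <- function(n_domains, break_fraction = 0,
                                         calpha_only_fraction = 0,
                                         seed = 1L, dir = tempfile("pdb"),
                                         n_res = 10L, gap_size = 6.0) {
  stopifnot(break_fraction >= 0, break_fraction <= 1,
            calpha_only_fraction >= 0, calpha_only_fraction <= 1,
            n_res >= 2)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  with_break <- runif(n_domains) < break_fraction
  ca_only <- runif(n_domains) < calpha_only_fraction
  break_after <- ifelse(with_break, sample(seq_len(n_res - 1L), n_domains,
                                           replace = TRUE), NA_integer_)
  files <- file.path(dir, sprintf("synthetic_dom_%03d.pdb", seq_len(n_domains)))
  for (k in seq_len(n_domains)) {
    x <- cumsum(c(0, rep(3.8, n_res - 1L)))
    if (with_break[k]) {
      ba <- break_after[k]
      x[(ba + 1L):n_res] <- x[(ba + 1L):n_res] + (gap_size - 3.8)
    }
    lines <- character(0); serial <- 0L
    for (r in seq_len(n_res)) {
      emit <- function(name, dx, dy) {
        serial <<- serial + 1L
        # canonical ATOM columns: name 13-16, altLoc 17, resName 18-20,
        # chain 22, resSeq 23-26, x/y/z 31-54
        sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                serial, name, "ALA", "A", r, x[r] + dx, dy, 0, 1, 0,
                substr(trimws(name), 1, 1))
      }
      if (ca_only[k]) {
        lines <- c(lines, emit(" CA ", 0, 0))
      } else {
        lines <- c(lines, emit(" N  ", -0.5, 0.4), emit(" CA ", 0, 0),
                   emit(" C  ", 0.5, 0.4), emit(" O  ", 0.6, 1.5))
      }
    }
    writeLines(c(lines, "END"), files[k])
  }
  data.frame(file = files, calpha_only = ca_only, break_after = break_after,
             stringsAsFactors = FALSE)
}
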