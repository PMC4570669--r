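# Configuration and end-to-end orchestration: simulate inputs, calibrate,
# build networks, analyse, run the age analyses, write a manifest.

#' Write a synthetic input bundle to disk
#'
#' Materialises a [synthetic_spec()] as the TSV files [run_pipeline()]
#' consumes: annotation, one score table per method, ages, plus
#' ground-truth tables (planted bridges with per-method visibility, planted
#' communities) and optional PDB coordinate fixtures.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created).
#' @param coordinates if TRUE also write PDB fixtures for the QC stage.
#' @return a [pipeline_config()] ready for [run_pipeline()], with the truth
#'   tables attached as attribute `truth`.
#' @export
simulate_inputs <- function(spec, dir, coordinates = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- generate_hierarchy(spec)
  bridges <- plant_bridges(spec)
  tabs <- generate_score_tables(spec, ann, bridges)
  bridges_vis <- attr(tabs, "bridges")
  ages <- generate_ages(spec, ann, bridges)
  comms <- planted_communities(spec)

  wtsv <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  ann_path <- wtsv(ann, "annotation.tsv")
  ages_path <- wtsv(ages, "ages.tsv")
  wtsv(bridges_vis, "planted_bridges.tsv")
  wtsv(comms, "planted_communities.tsv")
  score_paths <- vapply(names(tabs), function(m)
    wtsv(as.data.frame(tabs[[m]]), sprintf("scores_%s.tsv", m)), "")
  coord_dir <- NULL
  if (coordinates) {
    coord_dir <- file.path(dir, "coords")
    generate_coordinate_fixtures(nrow(ann), break_fraction = 0.1,
                                 calpha_only_fraction = 0.1,
                                 seed = spec$seed, dir = coord_dir)
  }
  methods <- lapply(spec$methods, function(m)
    list(orientation = m$orientation, weight_rule = m$weight_rule))
  cfg <- pipeline_config(
    annotation = ann_path, ages = ages_path,
    scores = setNames(score_paths, names(tabs)),
    methods = methods, coordinates = coord_dir,
    output_dir = file.path(dir, "out"), seed = spec$seed)
  attr(cfg, "truth") <- list(bridges = bridges_vis, communities = comms,
                             annotation = ann, ages = ages)
  cfg
}

#' Pipeline configuration
#'
#' Declares input paths, per-method conventions and analysis settings for
#' [run_pipeline()]. All referenced inputs must exist when the pipeline
#' starts.
#'
#' @param annotation path to the domain annotation TSV.
#' @param scores named character vector of score TSV paths, one per method.
#' @param ages path to the fold-age TSV (`NULL` disables the age stage).
#' @param methods named list per method: `list(orientation =, weight_rule =)`.
#' @param coordinates optional directory of PDB files for the QC stage.
#' @param thresholds static posterior thresholds, sorted, within (0, 1\].
#' @param dynamic_grid strictly decreasing grid for the dynamic sweep.
#' @param analysis_threshold threshold for multiplicity/age analyses.
#' @param louvain_seed,louvain_restarts community-detection settings.
#' @param output_dir artifact directory.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, scores, ages = NULL,
                            methods,
                            coordinates = NULL,
                            thresholds = seq(0.5, 0.9, by = 0.1),
                            dynamic_grid = seq(1, 0.5, by = -0.01),
                            analysis_threshold = 0.6,
                            louvain_seed = 1L, louvain_restarts = 10L,
                            output_dir = "foldbridges_out", seed = 1L) {
  if (is.unsorted(thresholds) || any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must be sorted and lie in (0, 1]")
  if (any(diff(dynamic_grid) >= 0)) stop("dynamic_grid must be strictly decreasing")
  if (!analysis_threshold %in% thresholds)
    stop("analysis_threshold must be one of the static thresholds")
  if (is.null(names(scores)) || !all(names(scores) %in% names(methods)))
    stop("every score table needs a method entry in `methods`")
  for (p in c(annotation, ages, unname(scores)))
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", p)
  if (!is.null(coordinates) && !dir.exists(coordinates))
    stop("coordinate directory does not exist: ", coordinates)
  structure(list(annotation = annotation, scores = scores, ages = ages,
                 methods = methods, coordinates = coordinates,
                 thresholds = thresholds, dynamic_grid = dynamic_grid,
                 analysis_threshold = analysis_threshold,
                 louvain_seed = as.integer(louvain_seed),
                 louvain_restarts = as.integer(louvain_restarts),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full fold-space pipeline
#'
#' Stages: optional coordinate QC; per-method calibration (all-alpha
#' partition) with the cutoffs table; collapse to fold level with edge
#' weights; static network sweep (methods + consensus per threshold) and
#' per-method dynamic sequences; centralities, central/peripheral
#' partitions, communities and statistics per network plus pivotal folds;
#' edge-multiplicity and age analyses at the analysis threshold. A JSON
#' manifest records configuration, seeds and per-stage counts. On a stage
#' failure the completed outputs remain and a `FAILED` marker names the
#' stage.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `calibrations`,
#'   `cutoff_table`, `networks`, `dynamics`, `centralities`, `partitions`,
#'   `communities`, `statistics`, `pivotal`, `multiplicity`, `age_bins`,
#'   `age_report`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("foldbridges")),
                   seed = config$seed,
                   thresholds = config$thresholds,
                   analysis_threshold = config$analysis_threshold,
                   methods = names(config$scores),
                   counts = list())
  stage <- "setup"
  res <- list()
  tryCatch({
    stage <- "read_inputs"
    ann <- read.delim(config$annotation, stringsAsFactors = FALSE)
    ages <- if (!is.null(config$ages))
      validate_ages(read.delim(config$ages, stringsAsFactors = FALSE))
    tabs <- lapply(names(config$scores), function(m)
      score_table(read.delim(config$scores[[m]], stringsAsFactors = FALSE),
                  method = m,
                  orientation = config$methods[[m]]$orientation))
    names(tabs) <- names(config$scores)
    manifest$counts$domains <- nrow(ann)
    manifest$counts$folds <- length(unique(ann$fold))
    manifest$counts$pairs_per_method <- vapply(tabs, nrow, 0L)

    if (!is.null(config$coordinates)) {
      stage <- "qc"
      files <- list.files(config$coordinates, pattern = "\\.pdb$",
                          full.names = TRUE)
      qc <- qc_domains(files)
      write.table(qc, file.path(out, "coordinate_qc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$counts$qc_flagged <- sum(!qc$keep)
      res$qc <- qc
    }

    stage <- "calibrate"
    fold_of <- setNames(ann$fold, ann$domain_id)
    cls_of <- setNames(ann$class, ann$domain_id)
    calsets <- list(); collapsed <- list()
    for (m in names(tabs)) {
      tab <- tabs[[m]]
      sib <- fold_of[tab$domain_i] == fold_of[tab$domain_j]
      alpha <- cls_of[tab$domain_i] == "a" | cls_of[tab$domain_j] == "a"
      if (!any(alpha) || all(alpha)) alpha <- NULL  # unpartitioned universe
      sel <- select_score_by_auc(tab, sib)
      cs <- fit_calibration(tab[[sel$score]], sib, alpha, method = m,
                            orientation = attr(tab, "orientation"))
      calsets[[m]] <- cs
      post <- score_posteriors(tab, cs, ann, score_col = sel$score)
      coll <- collapse_posteriors(post, ann, level = "fold")
      coll$weight <- assign_edge_weight(config$methods[[m]]$weight_rule, coll)
      collapsed[[m]] <- coll
    }
    cutoffs <- calibration_table(calsets, levels = config$thresholds)
    write.table(cutoffs, file.path(out, "score_cutoffs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$calibrations <- calsets; res$cutoff_table <- cutoffs
    res$collapsed <- collapsed

    stage <- "build_networks"
    nodes <- fold_node_table(ann, ages)
    nets <- build_network_sweep(collapsed, config$thresholds, nodes = nodes)
    net_dir <- file.path(out, "networks")
    if (!dir.exists(net_dir)) dir.create(net_dir)
    for (nm in names(nets)) {
      safe <- gsub("@", "_at_", nm, fixed = TRUE)
      write_edge_list(nets[[nm]], file.path(net_dir, paste0(safe, ".tsv")))
      write_graphml(nets[[nm]], file.path(net_dir, paste0(safe, ".graphml")))
    }
    dynamics <- lapply(names(collapsed), function(m)
      build_dynamic_sequence(collapsed[[m]], config$dynamic_grid,
                             nodes = nodes, method = m))
    names(dynamics) <- names(collapsed)
    for (m in names(dynamics))
      write_graphml(dynamics[[m]],
                    file.path(net_dir, sprintf("%s_dynamic.graphml", m)))
    manifest$counts$static_networks <- length(nets)
    manifest$counts$edges_per_network <- vapply(nets, function(n) nrow(n$edges), 0L)
    res$networks <- nets; res$dynamics <- dynamics

    stage <- "analyze"
    cents <- lapply(nets, centralities)
    parts <- lapply(cents, partition_central_peripheral)
    comms <- lapply(nets, function(n)
      suppressWarnings(detect_communities(n, seed = config$louvain_seed,
                                          restarts = config$louvain_restarts)))
    stats_rows <- lapply(names(nets), function(nm) {
      thr <- nets[[nm]]$threshold
      sibs <- nets[names(nets) != nm]
      sibs <- sibs[vapply(sibs, function(s)
        isTRUE(all.equal(s$threshold, thr)) && s$method != "consensus", TRUE)]
      network_statistics(nets[[nm]], siblings = sibs)
    })
    stats <- do.call(rbind, stats_rows)
    write.table(stats, file.path(out, "network_statistics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cent_dir <- file.path(out, "centralities")
    if (!dir.exists(cent_dir)) dir.create(cent_dir)
    for (nm in names(cents)) {
      safe <- gsub("@", "_at_", nm, fixed = TRUE)
      write.table(cents[[nm]], file.path(cent_dir, paste0(safe, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pivotal <- identify_pivotal(parts)
    writeLines(pivotal, file.path(out, "pivotal_folds.txt"))
    manifest$counts$pivotal <- length(pivotal)
    res$centralities <- cents; res$partitions <- parts
    res$communities <- comms; res$statistics <- stats; res$pivotal <- pivotal

    if (!is.null(ages)) {
      stage <- "ages"
      thr <- config$analysis_threshold
      per_method <- nets[grep("^consensus@", names(nets), invert = TRUE)]
      per_method <- per_method[vapply(per_method, function(n)
        isTRUE(all.equal(n$threshold, thr)), TRUE)]
      mult <- edge_multiplicity(per_method, nodes = nodes)
      bins <- edge_age_differences(mult, ages)
      write.table(bins$summary, file.path(out, "age_difference_bins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report <- central_peripheral_age_report(parts, ages)
      write.table(report, file.path(out, "central_peripheral_ages.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$counts$multiplicity_histogram <- as.list(mult$histogram)
      res$multiplicity <- mult; res$age_bins <- bins; res$age_report <- report
    }

    stage <- "manifest"
    manifest$completed <- TRUE
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
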