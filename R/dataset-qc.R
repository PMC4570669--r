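#' Filter domain records by ASTRAL aerospaci quality score
#'
#' Removes domains whose aerospaci score falls below the threshold
#' (default 0.4, so a score of exactly 0.4 is retained). The rejection log
#' names the rule applied to each removed record.
#'
#' @param records data.frame with at least `domain_id` and `aerospaci`.
#' @param aerospaci_min removal threshold; records with
#'   `aerospaci < aerospaci_min` are dropped.
#' @return list with `retained` (data.frame) and `log` (data.frame with
#'   `domain_id`, `rule`, `value`).
#' @export
filter_by_quality <- function(records, aerospaci_min = 0.4) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(list(retained = records,
                log = data.frame(domain_id = character(0), rule = character(0),
                                 value = numeric(0), stringsAsFactors = FALSE)))
  }
  if (!"aerospaci" %in% names(records) || anyNA(records$aerospaci))
    stop("aerospaci score missing for one or more records; refusing to filter")
  drop <- records$aerospaci < aerospaci_min
  log <- data.frame(
    domain_id = if ("domain_id" %in% names(records))
      records$domain_id[drop] else which(drop),
    rule = rep(sprintf("aerospaci < %s", format(aerospaci_min)), sum(drop)),
    value = records$aerospaci[drop], stringsAsFactors = FALSE)
  retained <- records[!drop, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, log = log)
}

#' Detect chain breaks along an ordered C-alpha trace
#'
#' A break is a pair of consecutive C-alpha atoms strictly further apart
#' than the threshold (default 4.3 angstrom; a gap of exactly 4.3 is not a
#' break).
#'
#' @param coords numeric matrix, one row per residue in chain order,
#'   columns x/y/z.
#' @param gap_threshold distance threshold in angstrom.
#' @return integer vector of indices `i` such that residues `i` and `i+1`
#'   are further apart than the threshold.
#' @export
detect_chain_breaks <- function(coords, gap_threshold = 4.3) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) {
    warning("fewer than 2 residues; no breaks detectable")
    return(integer(0))
  }
  d <- sqrt(rowSums(diff(coords)^2))
  which(d > gap_threshold)
}

#' Read the ordered C-alpha trace of a single-chain PDB file
#'
#' Uses bio3d to parse ATOM records; alternate locations keep the first
#' altloc, residue order is honoured as given.
#'
#' @param file path to a PDB file.
#' @return list with `coords` (C-alpha coordinate matrix) and `calpha_only`
#'   (TRUE when the file holds no non-C-alpha atoms).
#' @export
read_calpha_trace <- function(file) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", "A"), , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  list(coords = as.matrix(ca[, c("x", "y", "z")]),
       calpha_only = all(atoms$elety == "CA"))
}

#' Coordinate-level QC over a set of domain structure files
#'
#' Flags each domain for omission when its chain has at least one break
#' (consecutive C-alpha atoms further than `gap_threshold` apart) or when
#' the file contains only C-alpha atoms, mirroring the preprocessing the
#' alignment methods require.
#'
#' @param files character vector of PDB paths.
#' @param gap_threshold chain-break threshold in angstrom.
#' @return data.frame `file`, `n_res`, `calpha_only`, `n_breaks`,
#'   `break_positions` (comma-separated), `keep`.
#' @export
qc_domains <- function(files, gap_threshold = 4.3) {
  rows <- lapply(files, function(f) {
    tr <- read_calpha_trace(f)
    br <- if (nrow(tr$coords) < 2) integer(0)
    else detect_chain_breaks(tr$coords, gap_threshold)
    data.frame(file = f, n_res = nrow(tr$coords),
               calpha_only = tr$calpha_only, n_breaks = length(br),
               break_positions = paste(br, collapse = ","),
               keep = !tr$calpha_only && length(br) == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
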