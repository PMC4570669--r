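#' Sparse symmetric pairwise score table for one alignment method
#'
#' Stores each unordered domain pair once (`domain_i` < `domain_j` after
#' canonicalisation) together with one or more named score columns. The
#' declared orientation says whether greater scores mean more similar
#' (`"similarity"`) or less similar (`"distance"`, e.g. an elastic metric);
#' all downstream calibration flips distance scores internally so that
#' "greater = more similar" holds everywhere.
#'
#' @param df data.frame with character columns `domain_i`, `domain_j` and at
#'   least one numeric score column.
#' @param method method name.
#' @param orientation `"similarity"` or `"distance"`.
#' @return the data.frame, classed `score_table`, with attributes `method`
#'   and `orientation`.
#' @export
score_table <- function(df, method, orientation = c("similarity", "distance")) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(df), all(c("domain_i", "domain_j") %in% names(df)))
  if (any(df$domain_i == df$domain_j))
    stop("score table contains self-pairs")
  swap <- df$domain_i > df$domain_j
  if (any(swap)) {
    tmp <- df$domain_i[swap]
    df$domain_i[swap] <- df$domain_j[swap]
    df$domain_j[swap] <- tmp
  }
  key <- paste(df$domain_i, df$domain_j)
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    sc <- setdiff(names(df), c("domain_i", "domain_j"))
    chk <- stats::aggregate(dup[sc], by = list(key = paste(dup$domain_i, dup$domain_j)),
                            FUN = function(x) max(x) - min(x))
    if (any(unlist(chk[sc]) > 1e-12))
      stop("score table has conflicting duplicate entries for (i,j)/(j,i)")
    df <- df[!duplicated(key), ]
  }
  score_cols <- setdiff(names(df), c("domain_i", "domain_j"))
  if (!length(score_cols) || !all(vapply(df[score_cols], is.numeric, TRUE)))
    stop("score table needs at least one numeric score column")
  structure(df, class = c("score_table", "data.frame"),
            method = method, orientation = orientation)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: method %s (%s-oriented), %d pairs, columns: %s\n",
              attr(x, "method"), attr(x, "orientation"), nrow(x),
              paste(setdiff(names(x), c("domain_i", "domain_j")),
                    collapse = ", ")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

score_columns <- function(tab) setdiff(names(tab), c("domain_i", "domain_j"))
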