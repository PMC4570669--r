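# Empirical-Bayes calibration of alignment scores to posterior probabilities
# of fold co-membership, and inversion of the posterior to score cutoffs.

#' Area under the ROC curve for sibling discrimination
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a randomly
#' chosen sibling pair outscores a randomly chosen unrelated pair, with ties
#' counted half.
#'
#' @param scores numeric scores (similarity-oriented).
#' @param sibling logical, TRUE for fold-sibling pairs.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, sibling) {
  stopifnot(length(scores) == length(sibling), any(sibling), any(!sibling))
  r <- rank(scores)
  n1 <- sum(sibling); n0 <- sum(!sibling)
  (sum(r[sibling]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select a method's score column by AUROC
#'
#' When an alignment method reports several candidate scores, the one
#' discriminating fold siblings from unrelated pairs best (largest AUROC)
#' is used for calibration. Distance-oriented tables are sign-flipped before
#' evaluation. Constant columns score 0.5 with a warning; ties are broken by
#' column order.
#'
#' @param tab a [score_table()].
#' @param sibling logical vector, one entry per pair in `tab`.
#' @return list with `score` (chosen column), `auroc`, and `all` (named
#'   AUROC vector over candidates).
#' @export
select_score_by_auc <- function(tab, sibling) {
  stopifnot(inherits(tab, "score_table"), length(sibling) == nrow(tab))
  cols <- score_columns(tab)
  flip <- if (attr(tab, "orientation") == "distance") -1 else 1
  aucs <- vapply(cols, function(cn) {
    x <- flip * tab[[cn]]
    if (length(unique(x)) < 2L) {
      warning("score column '", cn, "' has no variance; AUROC set to 0.5")
      return(0.5)
    }
    auroc(x, sibling)
  }, numeric(1))
  best <- which.max(aucs)  # which.max keeps the first of tied maxima
  list(score = cols[best], auroc = unname(aucs[best]), all = aucs)
}

# --- calibration model ------------------------------------------------------

new_calibration_model <- function(sib, unr, method, partition, orientation) {
  sib <- sort(sib); unr <- sort(unr)
  grid <- sort(unique(c(sib, unr)))
  structure(list(method = method, partition = partition,
                 orientation = orientation,
                 prior_same = length(sib) / (length(sib) + length(unr)),
                 prior_diff = length(unr) / (length(sib) + length(unr)),
                 sib = sib, unr = unr, grid = grid,
                 eval_grid = grid[-length(grid)]),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("calibration_model: method %s, partition %s, ",
                     "%d sibling / %d unrelated pairs, prior_same %.4g\n"),
              x$method, x$partition, length(x$sib), length(x$unr),
              x$prior_same))
  invisible(x)
}

# count of sorted values strictly greater than each s (vectorised)
n_greater <- function(sorted, s) length(sorted) - findInterval(s, sorted)

# empirical survival P(S > s) with strict inequality
emp_survival <- function(sorted, s) n_greater(sorted, s) / length(sorted)

#' Fit the empirical posterior-probability calibration
#'
#' Estimates, per partition, the posterior probability that two domains are
#' representatives of the same fold given that their similarity exceeds a
#' candidate threshold \eqn{\bar s}:
#' \deqn{P(F=1 \mid S>\bar s) = \frac{P(S>\bar s\mid F=1)\,P(F=1)}
#'   {P(S>\bar s\mid F=1)P(F=1) + P(S>\bar s\mid F=0)P(F=0)}}
#' The priors are the observed proportions of sibling and unrelated pairs in
#' the partition and the conditionals are empirical survival proportions
#' (strict inequality). Following the significance convention for all-alpha
#' comparisons, pairs involving an all-alpha domain are calibrated separately
#' from all other pairs when `alpha_involved` is supplied, yielding one model
#' per partition.
#'
#' @param scores raw scores on the method's own scale.
#' @param sibling logical, TRUE when the pair shares a fold.
#' @param alpha_involved optional logical, TRUE when either domain is
#'   all-alpha; `NULL` fits a single pooled model.
#' @param method method name (metadata).
#' @param orientation `"similarity"` or `"distance"` (distance scores are
#'   sign-flipped internally).
#' @return object of class `calibration_set`: list with `method`,
#'   `orientation` and `models` (named list of `calibration_model`s, keyed
#'   `alpha_involved` / `other`, or `all` when unpartitioned).
#' @export
fit_calibration <- function(scores, sibling, alpha_involved = NULL,
                            method = "method",
                            orientation = c("similarity", "distance")) {
  orientation <- match.arg(orientation)
  stopifnot(length(scores) == length(sibling))
  x <- if (orientation == "distance") -scores else scores
  if (anyNA(x)) stop("scores contain NA")
  parts <- if (is.null(alpha_involved)) list(all = rep(TRUE, length(x)))
  else {
    stopifnot(length(alpha_involved) == length(x))
    list(alpha_involved = alpha_involved, other = !alpha_involved)
  }
  models <- list()
  for (pn in names(parts)) {
    sel <- parts[[pn]]
    if (!any(sel)) next
    if (!any(sibling[sel]))
      stop("partition '", pn, "' has zero sibling pairs; posterior undefined")
    if (all(sibling[sel]))
      stop("partition '", pn, "' has zero unrelated pairs; posterior undefined")
    models[[pn]] <- new_calibration_model(x[sel & sibling], x[sel & !sibling],
                                          method, pn, orientation)
  }
  structure(list(method = method, orientation = orientation, models = models),
            class = "calibration_set")
}

# posterior at internal-scale thresholds s (strict survival)
posterior_internal <- function(model, s) {
  s1 <- emp_survival(model$sib, s)
  s0 <- emp_survival(model$unr, s)
  num <- model$prior_same * s1
  den <- num + model$prior_diff * s0
  ifelse(den == 0, NA_real_, num / den)
}

#' Posterior probability at a candidate threshold
#'
#' Evaluates the fitted posterior \eqn{P(F=1 \mid S>\bar s)} at arbitrary
#' thresholds on the method's original scale. `NA` where no observed score
#' exceeds the threshold (the conditional is 0/0).
#'
#' @param model a `calibration_model`.
#' @param sbar thresholds on the original score scale.
#' @return posterior probabilities.
#' @export
posterior_at <- function(model, sbar) {
  stopifnot(inherits(model, "calibration_model"))
  s <- if (model$orientation == "distance") -sbar else sbar
  posterior_internal(model, s)
}

#' Posterior probability of individual alignments
#'
#' Each alignment's posterior is the calibration curve evaluated at the
#' largest observed candidate threshold strictly below the alignment's own
#' score, so that the strict-survival conditionals count the alignment
#' itself. Scores at or below the lowest observed score are evaluated at the
#' leftmost estimable point and flagged.
#'
#' @param model a `calibration_model`.
#' @param score alignment scores on the original scale.
#' @return posteriors in \[0, 1\], with logical attribute `flagged` marking
#'   scores below the observed support.
#' @export
posterior_of_alignment <- function(model, score) {
  stopifnot(inherits(model, "calibration_model"))
  x <- if (model$orientation == "distance") -score else score
  eg <- model$eval_grid
  if (!length(eg)) stop("calibration model has a single observed score; posterior inestimable")
  pos <- findInterval(x, eg)                       # count of eval grid <= x
  exact <- pos > 0L & eg[pmax(pos, 1L)] == x
  pos[exact] <- pos[exact] - 1L
  flagged <- pos == 0L
  pos[flagged] <- 1L
  out <- posterior_internal(model, eg[pos])
  attr(out, "flagged") <- flagged
  out
}

#' Invert the calibration: score cutoff for a posterior level
#'
#' Returns the smallest observed score \eqn{\bar s} such that every observed
#' score at or above it carries an alignment posterior of at least `p` (a
#' suffix condition that is well defined even where the raw empirical curve
#' is non-monotone in sparse regions). For distance-oriented methods the
#' cutoff is reported on the original scale as an upper limit.
#'
#' @param model a `calibration_model`.
#' @param p posterior level in (0, 1).
#' @return the cutoff, with attributes `limit` (`"lower"`/`"upper"`) and
#'   `attained`; `NA` with `attained = FALSE` when no score reaches `p`.
#' @export
threshold_for_posterior <- function(model, p) {
  stopifnot(inherits(model, "calibration_model"), p > 0, p < 1)
  g <- model$grid
  v <- posterior_of_alignment(model, if (model$orientation == "distance") -g else g)
  suffmin <- rev(cummin(rev(v)))
  idx <- which(suffmin >= p)
  limit <- if (model$orientation == "distance") "upper" else "lower"
  if (!length(idx)) {
    out <- NA_real_
    attr(out, "limit") <- limit; attr(out, "attained") <- FALSE
    return(out)
  }
  cut_internal <- g[idx[1]]
  out <- if (model$orientation == "distance") -cut_internal else cut_internal
  attr(out, "limit") <- limit; attr(out, "attained") <- TRUE
  out
}

#' Effective score cutoffs at a ladder of posterior levels
#'
#' Tabulates, per method and partition, the score threshold equivalent to
#' each posterior probability level (the style of a cutoffs supplementary
#' table), marking distance-oriented cutoffs as upper limits.
#'
#' @param calsets named list of `calibration_set` objects.
#' @param levels posterior levels (default 0.5 to 0.9).
#' @return data.frame `method`, `partition`, `posterior_level`, `cutoff`,
#'   `limit`, `attained`.
#' @export
calibration_table <- function(calsets, levels = seq(0.5, 0.9, by = 0.1)) {
  rows <- list()
  for (cs in calsets) for (m in cs$models) for (p in levels) {
    cut <- threshold_for_posterior(m, p)
    rows[[length(rows) + 1L]] <- data.frame(
      method = cs$method, partition = m$partition, posterior_level = p,
      cutoff = as.numeric(cut), limit = attr(cut, "limit"),
      attained = attr(cut, "attained"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
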