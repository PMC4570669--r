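#' Describe one pseudo alignment method for the synthetic generator
#'
#' Each method carries its score orientation, the truncated-normal parameters
#' of its sibling (same fold) and unrelated score distributions on \[0, 1\],
#' and the rule used to turn a raw score into an edge weight downstream.
#'
#' @param name method name.
#' @param orientation `"similarity"` (greater = more similar) or `"distance"`.
#' @param sibling,unrelated length-2 numeric `c(mean, sd)` of the truncated
#'   normal on \[0, 1\] that sibling / unrelated pairs draw scores from.
#' @param weight_rule edge-weight rule understood by [assign_edge_weight()]:
#'   `"score"` (use the raw score, TM-like) or `"inverse_distance"`.
#' @return a list of class `method_spec`.
#' @export
method_spec <- function(name, orientation = c("similarity", "distance"),
                        sibling, unrelated, weight_rule = "score") {
  orientation <- match.arg(orientation)
  stopifnot(length(sibling) == 2L, length(unrelated) == 2L,
            sibling[2] > 0, unrelated[2] > 0)
  if (orientation == "similarity" && sibling[1] <= unrelated[1])
    stop("similarity method: sibling mean must exceed unrelated mean")
  if (orientation == "distance" && sibling[1] >= unrelated[1])
    stop("distance method: sibling mean must be below unrelated mean")
  structure(list(name = name, orientation = orientation,
                 sibling = as.numeric(sibling),
                 unrelated = as.numeric(unrelated),
                 weight_rule = weight_rule),
            class = "method_spec")
}

#' Default pseudo-method panel
#'
#' Three similarity-oriented methods with TM-score-like distributions
#' (sibling N(0.6, 0.1), unrelated N(0.25, 0.08), truncated to \[0, 1\]) and
#' one distance-oriented method with mirrored parameters, so that handling of
#' elastic-metric-style scores is exercised everywhere.
#'
#' @return named list of [method_spec()] objects.
#' @export
default_methods <- function() {
  sim <- function(nm) method_spec(nm, "similarity",
                                  sibling = c(0.60, 0.10),
                                  unrelated = c(0.25, 0.08),
                                  weight_rule = "score")
  m <- list(sim("simA"), sim("simB"), sim("simC"),
            method_spec("distD", "distance",
                        sibling = c(0.40, 0.10),
                        unrelated = c(0.75, 0.08),
                        weight_rule = "inverse_distance"))
  setNames(m, vapply(m, `[[`, "", "name"))
}

#' Specification of a synthetic fold-space universe
#'
#' Defines the planted study conditions: a SCOP-like hierarchy (classes a-d,
#' folds, superfamilies, families, domains), per-method sibling/unrelated
#' score distributions, a set of planted inter-fold bridges preferentially
#' placed within five planted communities, per-method bridge visibility, and
#' age assortativity on bridge endpoints.
#'
#' One global `seed` drives independent child seeds for the hierarchy, the
#' bridge plant, the score tables and the ages, so each stage can be
#' regenerated on its own.
#'
#' @param n_classes number of SCOP-like classes, labelled `a`, `b`, ... The
#'   default 4 mirrors the four main SCOP classes.
#' @param folds_per_class folds per class.
#' @param domains_per_fold domains per fold; a single count or a length-2
#'   range sampled per fold.
#' @param methods named list of [method_spec()] objects.
#' @param bridge_fraction fraction of inter-fold pairs planted as bridges.
#' @param method_agreement probability that a planted bridge is visible to a
#'   given method.
#' @param intra_community_affinity,cross_community_affinity relative odds
#'   that a planted bridge is allocated to a same-community versus a
#'   cross-community fold pair (defaults 0.9 / 0.1: nine of ten bridges lie
#'   inside a planted community, yielding the five-block structure community
#'   detection must recover).
#' @param age_assortativity maximum |age difference| planted on bridge
#'   endpoints, in \[0, 1\].
#' @param seed integer master seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 4, folds_per_class = 10,
                           domains_per_fold = 3,
                           methods = default_methods(),
                           bridge_fraction = 0.05,
                           method_agreement = 0.8,
                           intra_community_affinity = 0.9,
                           cross_community_affinity = 0.1,
                           age_assortativity = 0.05,
                           seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || any(x < 1) || any(x != floor(x)))
      stop("invalid spec: ", nm, " must be a count >= 1")
  }
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("invalid spec: ", nm, " must lie in [0, 1]")
  }
  chk_count(n_classes, "n_classes"); chk_count(folds_per_class, "folds_per_class")
  chk_count(domains_per_fold, "domains_per_fold")
  if (length(domains_per_fold) > 2L)
    stop("invalid spec: domains_per_fold is a count or a length-2 range")
  chk_frac(bridge_fraction, "bridge_fraction")
  chk_frac(method_agreement, "method_agreement")
  chk_frac(intra_community_affinity, "intra_community_affinity")
  chk_frac(cross_community_affinity, "cross_community_affinity")
  chk_frac(age_assortativity, "age_assortativity")
  if (n_classes > 26) stop("invalid spec: at most 26 classes")
  if (!length(methods) || !all(vapply(methods, inherits, TRUE, "method_spec")))
    stop("invalid spec: methods must be method_spec objects")
  structure(list(n_classes = as.integer(n_classes),
                 folds_per_class = as.integer(folds_per_class),
                 domains_per_fold = as.integer(domains_per_fold),
                 methods = methods,
                 bridge_fraction = bridge_fraction,
                 method_agreement = method_agreement,
                 intra_community_affinity = intra_community_affinity,
                 cross_community_affinity = cross_community_affinity,
                 age_assortativity = age_assortativity,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# child seeds: independent per generator stage, derived from the master seed
child_seed <- function(spec, stage) {
  off <- c(hierarchy = 101L, bridges = 211L, scores = 307L, ages = 401L)[stage]
  (spec$seed * 1009L + off) %% 2147483647L
}

# truncated-normal sampling and tail probability on [a, b]
rtruncnorm <- function(n, mean, sd, a = 0, b = 1) {
  lo <- pnorm(a, mean, sd); hi <- pnorm(b, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Survival function of a normal distribution truncated to an interval
#'
#' @param x evaluation points.
#' @param mean,sd parameters of the untruncated normal.
#' @param a,b truncation interval.
#' @return `P(X > x)` for the truncated variable.
#' @export
truncnorm_survival <- function(x, mean, sd, a = 0, b = 1) {
  lo <- pnorm(a, mean, sd); hi <- pnorm(b, mean, sd)
  p <- (hi - pnorm(x, mean, sd)) / (hi - lo)
  pmin(1, pmax(0, p))
}

#' Analytic posterior-probability cutoff for a synthetic method
#'
#' For a method whose sibling and unrelated score distributions are the
#' spec's truncated normals, the posterior that a pair with score above
#' \eqn{\bar s} shares a fold is available in closed form from the two
#' survival functions and the prior odds. This inverts it: the score at
#' which the posterior equals `p`. Used as the ground truth the empirical
#' calibration must converge to.
#'
#' @param method a [method_spec()].
#' @param p target posterior in (0, 1).
#' @param prior_same prior probability that a pair shares a fold.
#' @return score cutoff on the method's original scale (an upper limit for
#'   distance-oriented methods).
#' @export
analytic_cutoff <- function(method, p, prior_same) {
  stopifnot(inherits(method, "method_spec"), p > 0, p < 1,
            prior_same > 0, prior_same < 1)
  dist <- method$orientation == "distance"
  # internal similarity scale: distances are negated
  surv <- function(pars) {
    if (dist) function(x) 1 - truncnorm_survival(-x, pars[1], pars[2]) # P(D < -x)
    else function(x) truncnorm_survival(x, pars[1], pars[2])
  }
  s1 <- surv(method$sibling); s0 <- surv(method$unrelated)
  post <- function(x) {
    num <- prior_same * s1(x)
    num / (num + (1 - prior_same) * s0(x))
  }
  rng <- if (dist) c(-1 + 1e-9, -1e-9) else c(1e-9, 1 - 1e-9)
  root <- uniroot(function(x) post(x) - p, rng, tol = 1e-10)$root
  if (dist) -root else root
}
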