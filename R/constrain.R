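#' Constrain a model with expression-proportional flux bounds
#'
#' Every gene-associated reaction gets a capacity ceiling proportional to the
#' expression of its highest-expressed associated gene: with
#' \eqn{E = } `roundUpTo(`max gene RPKM`, granularity)` and \eqn{B = k E},
#' an irreversible forward reaction (lower bound >= 0) is bounded to
#' \eqn{[0, \min(ub, B)]}, an irreversible backward reaction (upper bound <= 0)
#' to \eqn{[\max(lb, -B), 0]}, and a reversible reaction to
#' \eqn{[\max(lb, -B), \min(ub, B)]} — the enzyme's capacity limits it in either
#' direction, and constraining never widens a pre-existing bound. Reactions
#' without any gene association keep their bounds unchanged. A reaction whose
#' genes are all unexpressed (or absent from the profile) is closed to zero
#' flux.
#'
#' @param model a [MetabolicModel-class]; not modified.
#' @param profile an [ExpressionProfile-class].
#' @param config a [TargetingConfig-class]; `k` and `granularity` are used.
#' @return a new, constrained [MetabolicModel-class].
#' @examples
#' m <- makeFixtureModel("CHAIN3")
#' p <- expressionProfile("s", c(g1 = 37))
#' mc <- fullConstrain(m, p)
#' upperBounds(mc)[["R1"]]   # 0.0027 * 40 = 0.108
#' @export
fullConstrain <- function(model, profile, config = targetingConfig()) {
  validObject(model); validObject(profile); validObject(config)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  missing <- character(0)
  for (i in seq_len(nReactions(model))) {
    g <- model@genes[[i]]
    if (!length(g)) next
    missing <- c(missing, setdiff(g, names(profile@values)))
    E <- roundUpTo(.maxExpression(g, profile@values), config@granularity)
    B <- config@k * E
    if (lb[i] >= 0) {            # irreversible forward
      lb[i] <- 0
      ub[i] <- min(ub[i], B)
    } else if (ub[i] <= 0) {     # irreversible backward
      ub[i] <- 0
      lb[i] <- max(lb[i], -B)
    } else {                     # reversible: capacity limits both directions
      lb[i] <- max(lb[i], -B)
      ub[i] <- min(ub[i], B)
    }
  }
  missing <- unique(missing)
  if (length(missing))
    warning(sprintf(
      "%d gene(s) associated to reactions are absent from profile '%s' and were treated as unexpressed",
      length(missing), profile@sampleId), call. = FALSE)
  model@reactions$lower_bound <- lb
  model@reactions$upper_bound <- ub
  validObject(model)
  model
}

#' Calibrate the proportionality constant against an observed growth rate
#'
#' Finds `k` such that the optimal biomass flux of the expression-constrained
#' model matches an experimentally observed growth rate. Since widening the
#' expression bounds can only enlarge the feasible set, optimal growth is
#' non-decreasing in `k`, and the root is found by bisection on
#' \eqn{[10^{-6}, 1]}.
#'
#' @param model an (unconstrained) [MetabolicModel-class].
#' @param profile an [ExpressionProfile-class].
#' @param observedGrowth observed growth rate in 1/h (the biomass flux to
#'   reproduce); must be >= 0.
#' @param config a [TargetingConfig-class]; `solverTolerance` sets the match
#'   tolerance.
#' @param lower,upper bisection search interval for `k`.
#' @return the calibrated constant `k` (numeric scalar).
#' @examples
#' m <- makeFixtureModel("CHAIN3")
#' p <- expressionProfile("s", c(g1 = 37))
#' calibrateK(m, p, observedGrowth = 0.108)   # ~0.0027
#' @export
calibrateK <- function(model, profile, observedGrowth,
                       config = targetingConfig(), lower = 1e-6, upper = 1) {
  if (is.na(observedGrowth) || observedGrowth < 0)
    .validationError("observedGrowth must be a non-negative growth rate (1/h)")
  tol <- config@solverTolerance
  growthAt <- function(k) {
    cfg <- config; cfg@k <- k
    f <- suppressWarnings(fba(fullConstrain(model, profile, cfg), tol = tol))
    if (f@status != "optimal") 0 else f@objectiveValue
  }
  if (observedGrowth == 0) {
    warning("observed growth of 0 is reproduced by any sufficiently small k; returning the lower search bound",
            call. = FALSE)
    return(lower)
  }
  gU <- growthAt(upper)
  if (gU < observedGrowth - tol)
    .fwError(sprintf(
      "calibration infeasible: growth at k = %g is %.6g, below the observed %.6g",
      upper, gU, observedGrowth), "fw_calibration_error")
  gL <- growthAt(lower)
  if (gL >= observedGrowth - tol) {
    warning(sprintf("observed growth already reached at the lower search bound k = %g", lower),
            call. = FALSE)
    return(lower)
  }
  lo <- lower; hi <- upper
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    g <- growthAt(mid)
    if (abs(g - observedGrowth) <= tol) return(mid)
    if (g < observedGrowth) lo <- mid else hi <- mid
    if (hi - lo < 1e-14) break
  }
  (lo + hi) / 2
}
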