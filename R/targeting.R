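# Throttling reactions and the greedy selective-target search.

# Apply the throttle rule for one reaction given its baseline flux v:
#   v > 0: new upper bound fraction*v (lower bound capped to stay <= it)
#   v < 0: new lower bound fraction*v (upper bound capped to stay >= it)
#   v = 0: both bounds 0
# Returns the model with updated bounds.
.throttleBounds <- function(model, rid, v, fraction, zero = 1e-9) {
  i <- match(rid, reactionIds(model))
  lb <- model@reactions$lower_bound[i]
  ub <- model@reactions$upper_bound[i]
  if (v > zero) {
    ub <- min(ub, fraction * v)
    lb <- min(lb, ub)
  } else if (v < -zero) {
    lb <- max(lb, fraction * v)
    ub <- max(ub, lb)
  } else {
    lb <- 0; ub <- 0
  }
  model@reactions$lower_bound[i] <- lb
  model@reactions$upper_bound[i] <- ub
  model
}

#' Growth effect of throttling reactions
#'
#' Constrains each targeted reaction to `fraction` (default 10%) of its flux in
#' the supplied baseline distribution, re-solves by [pfba()], and reports the
#' ratio of the new to the baseline objective. A ratio equal to `fraction`
#' means the objective is fully coupled to at least one targeted reaction; a
#' ratio of 1 means alternative pathways fully compensate. Throttling to a
#' fraction rather than zero reflects that real inhibition (drugs, siRNA) is
#' partial, and that even essential reactions can often be strongly reduced
#' without proportional growth loss.
#'
#' @param model a [MetabolicModel-class].
#' @param baseline the [pfba()] distribution of `model` (status `"optimal"`).
#' @param targets character vector of reaction ids to throttle.
#' @param fraction retained fraction of baseline flux, in (0, 1).
#' @param tol LP tolerance.
#' @return a [BlockResult-class].
#' @examples
#' m <- fullConstrain(makeFixtureModel("CHAIN3"),
#'                    expressionProfile("s", c(g1 = 37)))
#' b <- pfba(m)
#' blockReactions(m, b, "R1")   # ratio 0.1: fully coupled chain
#' @export
blockReactions <- function(model, baseline, targets, fraction = 0.1, tol = 1e-7) {
  if (!(fraction > 0 && fraction < 1))
    .validationError("fraction must be in (0, 1)")
  if (baseline@status != "optimal")
    .contractError("baseline distribution must be optimal")
  unknown <- setdiff(targets, reactionIds(model))
  if (length(unknown))
    .validationError(sprintf("unknown target reaction(s): %s",
                             paste(unknown, collapse = ", ")))
  blocked <- model
  for (rid in targets)
    blocked <- .throttleBounds(blocked, rid, baseline@fluxes[[rid]], fraction)
  sol <- pfba(blocked, tol)
  bObj <- baseline@objectiveValue
  if (sol@status != "optimal") {
    warning("blocked model is not solvable; reporting a zero objective", call. = FALSE)
    blockedObj <- 0
  } else {
    blockedObj <- sol@objectiveValue
  }
  ratio <- if (bObj > 0) blockedObj / bObj else 1
  new("BlockResult", targeted = as.character(targets), ratio = ratio,
      baselineObjective = bObj, blockedObjective = blockedObj)
}

#' Screen reactions for differential growth effects between two groups
#'
#' For every reaction, computes the single-reaction throttling ratio
#' ([blockReactions()] at `config@blockFraction`) in each model of a target
#' group (e.g. cancer cell lines) and a reference group (e.g. healthy cells),
#' then compares the two groups of ratios with a Welch t-test. Reactions whose
#' throttling hurts the target group significantly more than the reference
#' group rise to the top.
#'
#' @param targetModels named list of pre-constrained [MetabolicModel-class]
#'   objects (>= 2).
#' @param referenceModels named list of pre-constrained models (>= 2).
#' @param reactions character vector of reaction ids to screen.
#' @param config a [TargetingConfig-class].
#' @return a data.frame with one row per reaction: per-model ratio columns,
#'   `mean_target`, `mean_reference`, `mean_diff` (reference minus target),
#'   `t` and `p`, sorted by ascending `p`.
#' @export
screenTargets <- function(targetModels, referenceModels, reactions,
                          config = targetingConfig()) {
  if (length(targetModels) < 2L || length(referenceModels) < 2L)
    .validationError("need at least 2 models per group")
  if (!length(reactions))
    return(data.frame(reaction_id = character(0), mean_target = numeric(0),
                      mean_reference = numeric(0), mean_diff = numeric(0),
                      t = numeric(0), p = numeric(0)))
  models <- c(targetModels, referenceModels)
  if (is.null(names(models)) || anyDuplicated(names(models)))
    .validationError("models must be uniquely named")
  grp <- rep(c("target", "reference"), c(length(targetModels), length(referenceModels)))
  baselines <- lapply(models, pfba, tol = config@solverTolerance)
  bad <- vapply(baselines, function(b) b@status != "optimal", logical(1))
  if (any(bad))
    .contractError(sprintf("model(s) not solvable: %s",
                           paste(names(models)[bad], collapse = ", ")))
  ratios <- vapply(seq_along(models), function(j) {
    vapply(reactions, function(rid)
      blockReactions(models[[j]], baselines[[j]], rid,
                     fraction = config@blockFraction,
                     tol = config@solverTolerance)@ratio, numeric(1))
  }, numeric(length(reactions)))
  ratios <- matrix(ratios, nrow = length(reactions),
                   dimnames = list(reactions, names(models)))
  stats <- t(vapply(seq_len(nrow(ratios)), function(i) {
    wt <- welchT(ratios[i, grp == "target"], ratios[i, grp == "reference"])
    c(t = wt$t, p = wt$p)
  }, c(t = 0, p = 0)))
  out <- data.frame(reaction_id = reactions,
                    as.data.frame(ratios, check.names = FALSE),
                    mean_target = rowMeans(ratios[, grp == "target", drop = FALSE]),
                    mean_reference = rowMeans(ratios[, grp == "reference", drop = FALSE]),
                    t = stats[, "t"], p = stats[, "p"],
                    check.names = FALSE, row.names = NULL)
  out$mean_diff <- out$mean_reference - out$mean_target
  out[order(out$p, out$reaction_id), , drop = FALSE]
}

#' Greedy search for a selective target set
#'
#' Heuristic search for a small set of reactions whose throttling halves the
#' predicted growth of a target cell while sparing a reference cell. Both
#' models (already expression-constrained) are solved by [pfba()]; candidate
#' reactions are ranked by decreasing difference between their flux magnitude
#' in the target and in the reference. Walking down that ranking, each
#' candidate is tentatively throttled to `config@blockFraction` of its original
#' (initial-baseline) flux in *both* models, on top of previously kept
#' constraints. The candidate is kept iff the target's cumulative relative
#' growth falls below `config@singleThreshold` and the reference's exceeds the
#' target's by more than `config@selectivityMargin`; otherwise the constraint
#' is released. The search stops as soon as the target's relative growth drops
#' to `config@stopRatio` (converged), or when candidates run out.
#'
#' Candidates with zero baseline flux in both models are skipped (throttling
#' them cannot change either ratio). Ranking ties break lexicographically by
#' reaction id, making the search fully deterministic.
#'
#' @param target pre-constrained [MetabolicModel-class] for the target cell.
#' @param reference pre-constrained model for the reference cell (same
#'   reaction set).
#' @param config a [TargetingConfig-class].
#' @return a [TargetSet-class] with the accepted reactions (in order), the full
#'   per-candidate decision trace, the final cumulative relative growths and
#'   the convergence flag.
#' @examples
#' m <- makeFixtureModel("SELECTIVE")
#' pr <- makeFixtureProfiles("SELECTIVE")
#' ts <- findTargetSet(fullConstrain(m, pr$target),
#'                     fullConstrain(m, pr$reference))
#' acceptedTargets(ts)   # "S": the synthesis route the target depends on
#' @export
findTargetSet <- function(target, reference, config = targetingConfig()) {
  tol <- config@solverTolerance
  bT <- pfba(target, tol); bR <- pfba(reference, tol)
  if (bT@status != "optimal" || bT@objectiveValue <= 0)
    .contractError("target model must be solvable with positive growth")
  if (bR@status != "optimal" || bR@objectiveValue <= 0)
    .contractError("reference model must be solvable with positive growth")
  common <- intersect(reactionIds(target), reactionIds(reference))
  vT <- bT@fluxes[common]; vR <- bR@fluxes[common]
  score <- if (config@rankSigned) vT - vR else abs(vT) - abs(vR)
  ranked <- common[order(-score, common)]

  curT <- target; curR <- reference
  relT <- 1; relR <- 1
  accepted <- character(0)
  converged <- FALSE
  rows <- list()
  zero <- 1e-9
  for (rid in ranked) {
    if (abs(vT[[rid]]) < zero && abs(vR[[rid]]) < zero) next
    tentT <- .throttleBounds(curT, rid, vT[[rid]], config@blockFraction)
    tentR <- .throttleBounds(curR, rid, vR[[rid]], config@blockFraction)
    sT <- pfba(tentT, tol); sR <- pfba(tentR, tol)
    rT <- if (sT@status == "optimal") sT@objectiveValue / bT@objectiveValue else 0
    rR <- if (sR@status == "optimal") sR@objectiveValue / bR@objectiveValue else 0
    keep <- (rT < config@singleThreshold) && ((rR - rT) > config@selectivityMargin)
    rows[[length(rows) + 1L]] <- data.frame(
      reaction_id = rid, target_ratio_after = rT, reference_ratio_after = rR,
      accepted = keep, stringsAsFactors = FALSE)
    if (keep) {
      curT <- tentT; curR <- tentR
      relT <- rT; relR <- rR
      accepted <- c(accepted, rid)
      if (relT <= config@stopRatio) { converged <- TRUE; break }
    }
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(0), target_ratio_after = numeric(0),
               reference_ratio_after = numeric(0), accepted = logical(0))
  new("TargetSet", accepted = accepted, trace = trace,
      finalTargetRatio = relT, finalReferenceRatio = relR,
      converged = converged)
}
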