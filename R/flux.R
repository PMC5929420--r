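# Flux computation: FBA, parsimonious FBA, alternative-optima sampling.

.lpParts <- function(model) {
  list(S = as.matrix(stoichMatrix(model)),
       lb = model@reactions$lower_bound,
       ub = model@reactions$upper_bound,
       ids = reactionIds(model),
       oi = match(objectiveId(model), reactionIds(model)))
}

.emptyFlux <- function(status) {
  new("FluxDistribution", fluxes = stats::setNames(numeric(0), character(0)),
      objectiveValue = NA_real_, status = status)
}

# lower bound on the objective flux that fixes it at its optimum z*
# (>= (1 - tol) z*, the numerically robust form of "equality")
.fixObjectiveLB <- function(lb, oi, z, tol) {
  lb[oi] <- max(lb[oi], if (z >= 0) (1 - tol) * z else (1 + tol) * z)
  lb
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction's flux subject to the steady-state
#' constraint \eqn{S v = 0} and the flux bounds. An infeasible or unbounded
#' model is reported through the `status` slot, never as an error.
#'
#' @param model a [MetabolicModel-class].
#' @param tol LP tolerance.
#' @return a [FluxDistribution-class].
#' @examples
#' m <- fullConstrain(makeFixtureModel("CHAIN3"),
#'                    expressionProfile("s", c(g1 = 37)))
#' objectiveValue(fba(m))   # 0.108
#' @export
fba <- function(model, tol = 1e-7) {
  p <- .lpParts(model)
  cvec <- numeric(length(p$ids)); cvec[p$oi] <- 1
  res <- .solveLP(cvec, p$S, rep(0, nrow(p$S)), p$lb, p$ub, maximize = TRUE)
  if (res$status != "optimal") return(.emptyFlux(res$status))
  new("FluxDistribution", fluxes = stats::setNames(res$x, p$ids),
      objectiveValue = res$x[p$oi], status = "optimal")
}

#' Parsimonious flux distribution (pFBA)
#'
#' Two-stage estimate: first the FBA optimum \eqn{z^*} is computed, then the
#' objective flux is fixed at (at least) \eqn{(1-\mathrm{tol})\,z^*} and the
#' total absolute flux \eqn{\sum_r |v_r|} is minimized via the standard split
#' of each flux into non-negative forward and backward components. The result
#' is the flux distribution that achieves maximal growth with minimal overall
#' enzyme usage; futile cycles carry zero flux.
#'
#' @inheritParams fba
#' @return a [FluxDistribution-class]; a non-optimal first stage is propagated
#'   unchanged.
#' @export
pfba <- function(model, tol = 1e-7) {
  base <- fba(model, tol)
  if (base@status != "optimal") return(base)
  p <- .lpParts(model)
  n <- length(p$ids)
  lb <- .fixObjectiveLB(p$lb, p$oi, base@objectiveValue, tol)
  # v = vplus - vminus, both >= 0; bounds inherited from the signed bounds
  lbp <- pmax(0, lb);   ubp <- pmax(0, p$ub)
  lbm <- pmax(0, -p$ub); ubm <- pmax(0, -lb)
  A <- cbind(p$S, -p$S)
  res <- .solveLP(rep(1, 2 * n), A, rep(0, nrow(p$S)),
                  c(lbp, lbm), c(ubp, ubm), maximize = FALSE)
  if (res$status != "optimal") return(.emptyFlux(res$status))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  new("FluxDistribution", fluxes = stats::setNames(v, p$ids),
      objectiveValue = v[p$oi], status = "optimal")
}

#' Sample alternative optimal flux distributions
#'
#' The FBA optimum usually sits on a face of the flux polytope, not at a single
#' point: many flux distributions achieve the same maximal growth. This sampler
#' characterises that optimal face by fixing the objective at its optimum and
#' repeatedly maximizing a random linear objective (i.i.d. standard-normal
#' coefficients over reactions), collecting the resulting vertex solutions.
#' Per-reaction means and standard deviations across the sample summarise how
#' determined each flux is; a uniquely determined flux has sd 0.
#'
#' @inheritParams fba
#' @param n number of random-objective solutions to draw (>= 1).
#' @param seed RNG seed; identical seeds give bit-identical samples. The
#'   caller's RNG state is left untouched.
#' @return an [AltOptimaSample-class].
#' @export
sampleAlternativeOptima <- function(model, n = 100, seed = 1L, tol = 1e-7) {
  if (length(n) != 1L || is.na(n) || n < 1)
    .validationError("n must be a positive integer")
  n <- as.integer(n)
  base <- fba(model, tol)
  if (base@status != "optimal")
    .contractError(sprintf("model must be solvable before sampling (status: %s)",
                           base@status))
  p <- .lpParts(model)
  lb <- .fixObjectiveLB(p$lb, p$oi, base@objectiveValue, tol)
  nr <- length(p$ids)
  samples <- .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      cvec <- stats::rnorm(nr)
      res <- .solveLP(cvec, p$S, rep(0, nrow(p$S)), lb, p$ub, maximize = TRUE)
      if (res$status != "optimal")
        .fwError(sprintf("random-objective subproblem %d returned status %s", i, res$status),
                 "fw_solver_error")
      new("FluxDistribution", fluxes = stats::setNames(res$x, p$ids),
          objectiveValue = res$x[p$oi], status = "optimal")
    })
  })
  M <- do.call(rbind, lapply(samples, fluxes))
  mu <- colMeans(M)
  sdv <- if (n > 1) apply(M, 2, stats::sd) else stats::setNames(rep(0, nr), p$ids)
  new("AltOptimaSample", samples = samples, mean = mu, sd = sdv,
      n = n, seed = as.integer(seed))
}
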