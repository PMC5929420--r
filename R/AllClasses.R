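#' @import methods
#' @importFrom Matrix sparseMatrix Matrix colSums
NULL

#' Stoichiometric metabolic network
#'
#' An S4 container for a constraint-based metabolic model: a sparse
#' stoichiometric matrix (metabolites in rows, reactions in columns), per-reaction
#' flux bounds in mmol/gDW/h, flattened gene associations, and a single objective
#' (biomass) reaction. Exchange reactions are recognised by their single-metabolite
#' stoichiometry; by convention uptake is a negative flux on an exchange reaction.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`.
#' @slot reactions data.frame with columns `id`, `lower_bound`, `upper_bound`,
#'   `is_exchange`.
#' @slot genes list parallel to `reactions`; each element a character vector of
#'   gene identifiers (possibly empty) enabling that reaction.
#' @slot stoichiometry sparse `Matrix` (metabolites x reactions) of signed
#'   stoichiometric coefficients, with dimnames.
#' @slot objective character scalar, the id of the objective reaction.
#'
#' @seealso [readTabularModel()], [readSBMLModel()], [fba()], [fullConstrain()]
#' @export
setClass("MetabolicModel",
  representation(
    metabolites   = "data.frame",
    reactions     = "data.frame",
    genes         = "list",
    stoichiometry = "Matrix",
    objective     = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  if (!all(c("id", "name", "compartment") %in% names(met)))
    msgs <- c(msgs, "metabolites must have columns id, name, compartment")
  if (!all(c("id", "lower_bound", "upper_bound", "is_exchange") %in% names(rxn)))
    msgs <- c(msgs, "reactions must have columns id, lower_bound, upper_bound, is_exchange")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(met$id)) msgs <- c(msgs, "metabolite ids must be unique")
  if (any(!nzchar(met$id))) msgs <- c(msgs, "metabolite ids must be non-empty")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "reaction ids must be unique")
  if (any(rxn$lower_bound > rxn$upper_bound))
    msgs <- c(msgs, "every reaction must satisfy lower_bound <= upper_bound")
  if (length(object@genes) != nrow(rxn))
    msgs <- c(msgs, "genes list must be parallel to reactions")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, "stoichiometry must be |metabolites| x |reactions|")
  else {
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
      msgs <- c(msgs, "stoichiometry dimnames must match metabolite and reaction ids")
    nmet <- Matrix::colSums(S != 0)
    if (any(nmet == 0))
      msgs <- c(msgs, sprintf("reaction(s) with empty stoichiometry: %s",
                              paste(rxn$id[nmet == 0], collapse = ", ")))
    if (any(rxn$is_exchange != (nmet == 1)))
      msgs <- c(msgs, "is_exchange must mark exactly the single-metabolite reactions")
  }
  if (length(object@objective) != 1L || !(object@objective %in% rxn$id))
    msgs <- c(msgs, "objective must name exactly one existing reaction")
  if (length(msgs)) msgs else TRUE
})

#' Per-sample gene expression profile
#'
#' Maps gene identifiers to non-negative RPKM values for one sample; the sole
#' transcriptomic input to expression-based model constraining.
#'
#' @slot sampleId character scalar.
#' @slot values named numeric vector, gene id -> RPKM (>= 0).
#' @export
setClass("ExpressionProfile",
  representation(sampleId = "character", values = "numeric")
)

setValidity("ExpressionProfile", function(object) {
  msgs <- character()
  v <- object@values
  if (length(object@sampleId) != 1L) msgs <- c(msgs, "sampleId must be a scalar")
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
    msgs <- c(msgs, "values must be named by gene id")
  if (anyDuplicated(names(v))) msgs <- c(msgs, "gene ids must be unique")
  if (any(is.na(v)) || any(v < 0)) msgs <- c(msgs, "RPKM values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Method configuration
#'
#' All tunable constants of the constraining/targeting method in one object.
#' Defaults are the published operating point: bounds proportional to expression
#' with k = 0.0027 mmol/gDW/h per RPKM after rounding expression up to the next
#' multiple of 10; candidate reactions throttled to 10% of baseline flux; a
#' candidate kept when the target's relative growth falls below 0.9 and the
#' reference stays at least 0.05 above it; the search stops once target growth
#' halves; differential calls at FDR 0.01.
#'
#' @slot k numeric, proportionality constant (mmol/gDW/h per RPKM).
#' @slot granularity numeric, expression rounding granularity (RPKM).
#' @slot blockFraction numeric in (0,1), throttle fraction of baseline flux.
#' @slot singleThreshold numeric, target relative-growth acceptance threshold.
#' @slot selectivityMargin numeric, required reference-minus-target margin.
#' @slot stopRatio numeric, target relative growth at which the search stops.
#' @slot fdrLevel numeric, Benjamini-Hochberg significance level.
#' @slot solverTolerance numeric, LP feasibility/optimality tolerance.
#' @slot seed integer, default RNG seed for stochastic operations.
#' @slot rankSigned logical, rank candidates by signed flux difference instead
#'   of the default difference of magnitudes.
#' @seealso [targetingConfig()]
#' @export
setClass("TargetingConfig",
  representation(
    k = "numeric", granularity = "numeric", blockFraction = "numeric",
    singleThreshold = "numeric", selectivityMargin = "numeric",
    stopRatio = "numeric", fdrLevel = "numeric", solverTolerance = "numeric",
    seed = "integer", rankSigned = "logical"
  )
)

setValidity("TargetingConfig", function(object) {
  msgs <- character()
  if (object@k <= 0) msgs <- c(msgs, "k must be > 0")
  if (object@granularity <= 0) msgs <- c(msgs, "granularity must be > 0")
  if (!(object@blockFraction > 0 && object@blockFraction < object@stopRatio &&
        object@stopRatio < object@singleThreshold && object@singleThreshold < 1))
    msgs <- c(msgs, "need 0 < blockFraction < stopRatio < singleThreshold < 1")
  if (object@selectivityMargin < 0) msgs <- c(msgs, "selectivityMargin must be >= 0")
  if (object@fdrLevel <= 0 || object@fdrLevel >= 1) msgs <- c(msgs, "fdrLevel must be in (0,1)")
  if (object@solverTolerance <= 0) msgs <- c(msgs, "solverTolerance must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' A flux distribution
#'
#' One steady-state flux assignment (mmol/gDW/h per reaction) together with the
#' achieved objective value and the solver status. When `status` is not
#' `"optimal"` the flux vector is empty and the objective value is `NA`.
#'
#' @slot fluxes named numeric vector, reaction id -> flux.
#' @slot objectiveValue numeric scalar, flux of the objective reaction.
#' @slot status character, one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @export
setClass("FluxDistribution",
  representation(fluxes = "numeric", objectiveValue = "numeric", status = "character")
)

setValidity("FluxDistribution", function(object) {
  msgs <- character()
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    msgs <- c(msgs, "status must be optimal, infeasible or unbounded")
  if (object@status == "optimal") {
    if (length(object@fluxes) == 0L || is.null(names(object@fluxes)))
      msgs <- c(msgs, "optimal distributions must carry named fluxes")
    if (is.na(object@objectiveValue))
      msgs <- c(msgs, "optimal distributions must carry an objective value")
  }
  if (length(msgs)) msgs else TRUE
})

#' Sample of alternative optimal flux distributions
#'
#' Vertex solutions drawn from the optimal face of the flux polytope (objective
#' fixed at its optimum), with per-reaction mean and standard deviation.
#'
#' @slot samples list of [FluxDistribution-class] objects.
#' @slot mean named numeric, per-reaction mean flux across samples.
#' @slot sd named numeric, per-reaction standard deviation (0 when n = 1).
#' @slot n integer, number of samples.
#' @slot seed integer, RNG seed used.
#' @export
setClass("AltOptimaSample",
  representation(samples = "list", mean = "numeric", sd = "numeric",
                 n = "integer", seed = "integer")
)

setValidity("AltOptimaSample", function(object) {
  msgs <- character()
  if (object@n < 1L) msgs <- c(msgs, "n must be >= 1")
  if (length(object@samples) != object@n) msgs <- c(msgs, "samples must have length n")
  if (any(object@sd < 0)) msgs <- c(msgs, "standard deviations must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Result of throttling a set of reactions
#'
#' @slot targeted character vector of throttled reaction ids.
#' @slot ratio numeric, blocked-over-baseline objective ratio.
#' @slot baselineObjective numeric.
#' @slot blockedObjective numeric.
#' @export
setClass("BlockResult",
  representation(targeted = "character", ratio = "numeric",
                 baselineObjective = "numeric", blockedObjective = "numeric")
)

#' A selective target set
#'
#' Output of the greedy therapeutic-window search: the ordered accepted
#' reactions, the per-candidate decision trace, the final cumulative relative
#' growth of target and reference, and whether the stopping criterion
#' (target growth halved) was reached.
#'
#' @slot accepted character vector, accepted reaction ids in acceptance order.
#' @slot trace data.frame with columns `reaction_id`, `target_ratio_after`,
#'   `reference_ratio_after`, `accepted` (one row per tested candidate).
#' @slot finalTargetRatio numeric.
#' @slot finalReferenceRatio numeric.
#' @slot converged logical.
#' @export
setClass("TargetSet",
  representation(accepted = "character", trace = "data.frame",
                 finalTargetRatio = "numeric", finalReferenceRatio = "numeric",
                 converged = "logical")
)
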