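#' Accessors for MetabolicModel objects
#'
#' Read (and for bounds and objective, replace) the components of a
#' [MetabolicModel-class] without touching slots directly. Bound replacement
#' revalidates the object.
#'
#' @param object a `MetabolicModel`.
#' @param value replacement value: a numeric vector of length `nReactions(object)`
#'   (bounds) or a reaction id (objective).
#' @return `reactionIds`/`metaboliteIds` character vectors; `stoichMatrix` the
#'   sparse metabolites x reactions matrix; `lowerBounds`/`upperBounds` named
#'   numeric vectors; `geneAssociations` a named list of character vectors;
#'   `objectiveId` a character scalar; `isExchange` a named logical vector.
#' @name MetabolicModel-accessors
#' @aliases reactionIds metaboliteIds stoichMatrix lowerBounds upperBounds
#'   geneAssociations objectiveId isExchange
#' @examples
#' m <- makeFixtureModel("CHAIN3")
#' reactionIds(m)
#' lowerBounds(m)
NULL

#' @rdname MetabolicModel-accessors
#' @export
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("stoichMatrix", "MetabolicModel", function(object) object@stoichiometry)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("lowerBounds", "MetabolicModel", function(object)
  stats::setNames(object@reactions$lower_bound, object@reactions$id))

#' @rdname MetabolicModel-accessors
#' @export
setMethod("upperBounds", "MetabolicModel", function(object)
  stats::setNames(object@reactions$upper_bound, object@reactions$id))

#' @rdname MetabolicModel-accessors
#' @export
setMethod("lowerBounds<-", "MetabolicModel", function(object, value) {
  object@reactions$lower_bound <- unname(value)
  validObject(object)
  object
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("upperBounds<-", "MetabolicModel", function(object, value) {
  object@reactions$upper_bound <- unname(value)
  validObject(object)
  object
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("geneAssociations", "MetabolicModel", function(object)
  stats::setNames(object@genes, object@reactions$id))

#' @rdname MetabolicModel-accessors
#' @export
setMethod("objectiveId", "MetabolicModel", function(object) object@objective)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("objectiveId<-", "MetabolicModel", function(object, value) {
  object@objective <- value
  validObject(object)
  object
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("isExchange", "MetabolicModel", function(object)
  stats::setNames(object@reactions$is_exchange, object@reactions$id))

#' Number of reactions / metabolites in a model
#' @param object a `MetabolicModel`.
#' @return integer scalar.
#' @export
nReactions <- function(object) nrow(object@reactions)

#' @rdname nReactions
#' @export
nMetabolites <- function(object) nrow(object@metabolites)

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions\n",
              nMetabolites(object), nReactions(object)))
  cat(sprintf("  objective: %s\n", object@objective))
  cat(sprintf("  exchange reactions: %d; gene-associated reactions: %d\n",
              sum(object@reactions$is_exchange),
              sum(lengths(object@genes) > 0)))
})

#' Accessors for FluxDistribution objects
#' @param object a [FluxDistribution-class].
#' @return `fluxes` a named numeric vector; `objectiveValue` a numeric scalar;
#'   `solverStatus` a character scalar.
#' @name FluxDistribution-accessors
#' @aliases fluxes objectiveValue solverStatus
NULL

#' @rdname FluxDistribution-accessors
#' @export
setMethod("fluxes", "FluxDistribution", function(object) object@fluxes)

#' @rdname FluxDistribution-accessors
#' @export
setMethod("objectiveValue", "FluxDistribution", function(object) object@objectiveValue)

#' @rdname FluxDistribution-accessors
#' @export
setMethod("solverStatus", "FluxDistribution", function(object) object@status)

setMethod("show", "FluxDistribution", function(object) {
  cat(sprintf("FluxDistribution (%s): %d reactions, objective = %s\n",
              object@status, length(object@fluxes),
              format(object@objectiveValue, digits = 6)))
})

#' Accessors for ExpressionProfile objects
#' @param object an [ExpressionProfile-class].
#' @return `sampleId` a character scalar; `expressionValues` a named numeric
#'   vector of RPKM values.
#' @name ExpressionProfile-accessors
#' @aliases sampleId expressionValues
NULL

#' @rdname ExpressionProfile-accessors
#' @export
setMethod("sampleId", "ExpressionProfile", function(object) object@sampleId)

#' @rdname ExpressionProfile-accessors
#' @export
setMethod("expressionValues", "ExpressionProfile", function(object) object@values)

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile '%s': %d genes, median RPKM %.3g\n",
              object@sampleId, length(object@values),
              if (length(object@values)) stats::median(object@values) else NA))
})

#' Accessors for TargetSet objects
#' @param object a [TargetSet-class].
#' @return `acceptedTargets` a character vector of reaction ids in acceptance
#'   order; `decisionTrace` the per-candidate data.frame.
#' @name TargetSet-accessors
#' @aliases acceptedTargets decisionTrace
NULL

#' @rdname TargetSet-accessors
#' @export
setMethod("acceptedTargets", "TargetSet", function(object) object@accepted)

#' @rdname TargetSet-accessors
#' @export
setMethod("decisionTrace", "TargetSet", function(object) object@trace)

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet: %d accepted reaction(s)%s\n",
              length(object@accepted),
              if (length(object@accepted))
                paste0(" [", paste(object@accepted, collapse = ", "), "]") else ""))
  cat(sprintf("  target growth ratio %.4g, reference %.4g, converged: %s\n",
              object@finalTargetRatio, object@finalReferenceRatio, object@converged))
})

setMethod("show", "BlockResult", function(object) {
  cat(sprintf("BlockResult: %d reaction(s) throttled, objective ratio %.4g\n",
              length(object@targeted), object@ratio))
})

setMethod("show", "AltOptimaSample", function(object) {
  cat(sprintf("AltOptimaSample: n = %d (seed %d), %d reactions, max sd %.3g\n",
              object@n, object@seed, length(object@mean),
              if (length(object@sd)) max(object@sd) else NA))
})

setMethod("show", "TargetingConfig", function(object) {
  cat("TargetingConfig:\n")
  cat(sprintf("  k = %g mmol/gDW/h per RPKM, granularity = %g RPKM\n",
              object@k, object@granularity))
  cat(sprintf("  blockFraction = %g, thresholds %g / %g / %g\n",
              object@blockFraction, object@singleThreshold,
              object@selectivityMargin, object@stopRatio))
  cat(sprintf("  fdrLevel = %g, solverTolerance = %g, seed = %d\n",
              object@fdrLevel, object@solverTolerance, object@seed))
})
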