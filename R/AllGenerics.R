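#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("lowerBounds<-", function(object, value) standardGeneric("lowerBounds<-"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("upperBounds<-", function(object, value) standardGeneric("upperBounds<-"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("geneAssociations", function(object) standardGeneric("geneAssociations"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objectiveId", function(object) standardGeneric("objectiveId"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objectiveId<-", function(object, value) standardGeneric("objectiveId<-"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("isExchange", function(object) standardGeneric("isExchange"))

#' @rdname FluxDistribution-accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxDistribution-accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname FluxDistribution-accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @rdname ExpressionProfile-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname ExpressionProfile-accessors
#' @export
setGeneric("expressionValues", function(object) standardGeneric("expressionValues"))

#' @rdname TargetSet-accessors
#' @export
setGeneric("acceptedTargets", function(object) standardGeneric("acceptedTargets"))

#' @rdname TargetSet-accessors
#' @export
setGeneric("decisionTrace", function(object) standardGeneric("decisionTrace"))
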