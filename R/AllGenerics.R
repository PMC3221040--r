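#' @rdname ExcursionSet-class
#' @param object an object with peak/cluster content.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname ExcursionSet-class
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname ExcursionSet-class
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname SearchSpace-class
#' @param object a \code{SearchSpace}.
#' @export
setGeneric("resels", function(object) standardGeneric("resels"))

#' @rdname SimulationTruth-class
#' @param object a \code{SimulationTruth}.
#' @export
setGeneric("truePeaks", function(object) standardGeneric("truePeaks"))

#' @rdname ExcursionSet-class
setMethod("peaks", "ExcursionSet", function(object) object@peaks)
#' @rdname ExcursionSet-class
setMethod("clusters", "ExcursionSet", function(object) object@clusters)
#' @rdname ExcursionSet-class
setMethod("nClusters", "ExcursionSet",
    function(object) nrow(object@clusters))
#' @rdname ProcedureResult-class
#' @param object a \code{ProcedureResult}.
setMethod("peaks", "ProcedureResult", function(object) object@peaks)
#' @rdname ProcedureResult-class
setMethod("clusters", "ProcedureResult", function(object) object@clusters)
#' @rdname SearchSpace-class
setMethod("resels", "SearchSpace", function(object) object@resels)
#' @rdname SimulationTruth-class
setMethod("truePeaks", "SimulationTruth", function(object) object@mu)
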