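#' @include AllClasses.R
NULL

#' Accessors for respilab containers
#'
#' Small generics giving read access to the central containers without
#' touching slots: trace time grid, O2 concentrations, event table and
#' metadata; flux values and validity mask; state flows, titration series
#' and derived metrics of a profile.
#'
#' @param object a respilab S4 object.
#' @return the requested component; see the methods for details.
#' @name accessors
#' @aliases traceTime o2Concentration traceEvents traceMetadata
#'   fluxValues fluxValid stateFlows titrationSeries profileMetrics
NULL

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setGeneric("o2Concentration",
           function(object) standardGeneric("o2Concentration"))

#' @rdname accessors
#' @export
setGeneric("traceEvents", function(object) standardGeneric("traceEvents"))

#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))

#' @rdname accessors
#' @export
setGeneric("fluxValues", function(object) standardGeneric("fluxValues"))

#' @rdname accessors
#' @export
setGeneric("fluxValid", function(object) standardGeneric("fluxValid"))

#' @rdname accessors
#' @export
setGeneric("stateFlows", function(object) standardGeneric("stateFlows"))

#' @rdname accessors
#' @export
setGeneric("titrationSeries",
           function(object) standardGeneric("titrationSeries"))

#' @rdname accessors
#' @export
setGeneric("profileMetrics",
           function(object) standardGeneric("profileMetrics"))

setMethod("traceTime", "TraceSeries", function(object) object@time)
setMethod("o2Concentration", "TraceSeries", function(object) object@o2)
setMethod("traceEvents", "TraceSeries", function(object) object@events)
setMethod("traceMetadata", "TraceSeries", function(object) object@metadata)
setMethod("fluxValues", "FluxSeries", function(object) object@jv)
setMethod("fluxValid", "FluxSeries", function(object) object@valid)
setMethod("traceTime", "FluxSeries", function(object) object@time)
setMethod("stateFlows", "SuitProfile", function(object) object@flows)
setMethod("titrationSeries", "SuitProfile", function(object) object@titrations)
setMethod("profileMetrics", "SuitProfile", function(object) object@metrics)
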