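#' @name apexrip-accessors
#' @title Accessors for apexrip classes
#' @description Accessor generics for the core data classes. Slot access via
#'   \code{@} is considered internal; use these instead.
#' @param x an object of the documented class.
#' @return The requested component; see the individual class pages.
NULL

#' @rdname apexrip-accessors
#' @export
setGeneric("fpkmPre", function(x) standardGeneric("fpkmPre"))

#' @rdname apexrip-accessors
#' @export
setGeneric("fpkmPost", function(x) standardGeneric("fpkmPost"))

#' @rdname apexrip-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname apexrip-accessors
#' @export
setGeneric("biotypes", function(x) standardGeneric("biotypes"))

#' @rdname apexrip-accessors
#' @export
setGeneric("truePositives", function(x) standardGeneric("truePositives"))

#' @rdname apexrip-accessors
#' @export
setGeneric("falsePositives", function(x) standardGeneric("falsePositives"))

#' @rdname apexrip-accessors
#' @export
setGeneric("compartmentLabel",
           function(x) standardGeneric("compartmentLabel"))

#' @rdname apexrip-accessors
#' @export
setGeneric("chosenThreshold", function(x) standardGeneric("chosenThreshold"))

#' @rdname apexrip-accessors
#' @export
setGeneric("chosenJ", function(x) standardGeneric("chosenJ"))

#' @rdname apexrip-accessors
#' @export
setGeneric("enrichedGenes", function(x) standardGeneric("enrichedGenes"))

#' @rdname apexrip-accessors
#' @export
setGeneric("enrichedRecords", function(x) standardGeneric("enrichedRecords"))

#' @rdname apexrip-accessors
#' @export
setGeneric("callThreshold", function(x) standardGeneric("callThreshold"))

#' @rdname apexrip-accessors
#' @export
setGeneric("callAlpha", function(x) standardGeneric("callAlpha"))
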