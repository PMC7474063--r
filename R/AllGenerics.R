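#' Accessors for zonage S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return The slot content: a matrix, factor, character vector or list as
#'   appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))
#' @rdname accessors
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))
#' @rdname accessors
#' @export
setGeneric("consistentCells", function(x) standardGeneric("consistentCells"))
#' @rdname accessors
#' @export
setGeneric("runLabels", function(x) standardGeneric("runLabels"))
#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname accessors
#' @export
setGeneric("cellConditions", function(x) standardGeneric("cellConditions"))
#' @rdname accessors
#' @export
setGeneric("agingEffects", function(x) standardGeneric("agingEffects"))
#' @rdname accessors
#' @export
setGeneric("reversalFlags", function(x) standardGeneric("reversalFlags"))
#' @rdname accessors
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))
#' @rdname accessors
#' @export
setGeneric("markerIndicator", function(x) standardGeneric("markerIndicator"))

#' @rdname accessors
#' @export
setMethod("posteriorProbs", "AssignmentResult", function(x) x@posterior)
#' @rdname accessors
#' @export
setMethod("subtypeLabels", "AssignmentResult", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("consistentCells", "AssignmentResult", function(x) x@consistent)
#' @rdname accessors
#' @export
setMethod("runLabels", "AssignmentResult", function(x) x@runs)
#' @rdname accessors
#' @export
setMethod("cellLabels", "GroundTruth", function(x) x@cellLabels)
#' @rdname accessors
#' @export
setMethod("cellConditions", "GroundTruth", function(x) x@cellConditions)
#' @rdname accessors
#' @export
setMethod("agingEffects", "GroundTruth", function(x) x@agingEffects)
#' @rdname accessors
#' @export
setMethod("reversalFlags", "GroundTruth", function(x) x@reversalFlags)
#' @rdname accessors
#' @export
setMethod("markerSets", "GroundTruth", function(x) x@markerSets)
#' @rdname accessors
#' @export
setMethod("markerIndicator", "ZonationMarkers", function(x) x@indicator)

#' Arteriovenous subtype names
#'
#' The six endothelial subtypes along the arteriovenous axis, in canonical
#' order: two arterial (aEC1, aEC2), capillary (capEC), capillary-venous
#' (vcapEC), venous (vEC) and mixed arterial/venous (avEC).
#'
#' @return character(6)
#' @export
zonationSubtypes <- function() SUBTYPES
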