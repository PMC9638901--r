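#' Accessors for tilac S4 containers
#'
#' @param x a \code{\linkS4class{TilacCounts}}, \code{\linkS4class{TilacFit}}
#'   or \code{\linkS4class{TilacTests}} object.
#' @return \code{countTable}: the grouped count data.frame;
#'   \code{sampleDesign}: the labelling-design data.frame;
#'   \code{posteriorSummary}: the per-gene posterior summary;
#'   \code{globalRates}: the per-channel global-rate summary;
#'   \code{posteriorDraws}: the list of posterior draw matrices;
#'   \code{testResults}: the per-gene test-result data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("countTable", function(x) standardGeneric("countTable"))
#' @rdname accessors
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))
#' @rdname accessors
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))
#' @rdname accessors
#' @export
setGeneric("globalRates", function(x) standardGeneric("globalRates"))
#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))
#' @rdname accessors
#' @export
setGeneric("testResults", function(x) standardGeneric("testResults"))

#' @rdname accessors
#' @export
setMethod("countTable", "TilacCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("sampleDesign", "TilacCounts", function(x) x@design)
#' @rdname accessors
#' @export
setMethod("posteriorSummary", "TilacFit", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("globalRates", "TilacFit", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("posteriorDraws", "TilacFit", function(x) x@draws)
#' @rdname accessors
#' @export
setMethod("testResults", "TilacTests", function(x) x@results)
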