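#' @rdname CommunityMatrix-class
#' @param object,x an object.
#' @export
setGeneric("baMatrix", function(x) standardGeneric("baMatrix"))

#' @rdname CommunityMatrix-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname SampleDissimilarity-class
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' @rdname SampleDissimilarity-class
#' @export
setGeneric("indexName", function(x) standardGeneric("indexName"))

#' @rdname AssemblageHierarchy-class
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname AssemblageHierarchy-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AssemblageHierarchy-class
#' @export
setGeneric("hierarchyNodes", function(x) standardGeneric("hierarchyNodes"))

#' @rdname IndicatorTable-class
#' @export
setGeneric("indicatorTable", function(x) standardGeneric("indicatorTable"))

#' @rdname IndicatorTable-class
#' @export
setGeneric("headlineIndicators", function(x) standardGeneric("headlineIndicators"))
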