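#' @rdname sitePositions
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname tracts
#' @export
setGeneric("tracts", function(x, ...) standardGeneric("tracts"))

#' @rdname qcStats
#' @export
setGeneric("qcStats", function(x) standardGeneric("qcStats"))

#' @rdname regionTable
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname denseRegionLabels
#' @export
setGeneric("denseRegionLabels",
           function(x) standardGeneric("denseRegionLabels"))
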