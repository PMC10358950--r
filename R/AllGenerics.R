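#' @rdname VeinGraph-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname VeinGraph-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname VeinGraph-class
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname VeinGraph-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname VeinGraph-class
#' @export
setGeneric("selfLoopCount", function(x) standardGeneric("selfLoopCount"))

#' @rdname VeinGraph-class
#' @export
setGeneric("orphanCycleCount", function(x) standardGeneric("orphanCycleCount"))

#' @rdname VeinGraph-class
#' @export
setGeneric("cycleRank", function(x) standardGeneric("cycleRank"))

#' @rdname VeinGraph-class
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname computeNodeFeatures
#' @export
setGeneric("computeNodeFeatures", function(x, ...) standardGeneric("computeNodeFeatures"))

#' @rdname VeinGraph-class
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("homographyMatrix", function(x) standardGeneric("homographyMatrix"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("areaScale", function(x) standardGeneric("areaScale"))
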