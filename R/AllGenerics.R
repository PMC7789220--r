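#' @rdname OmicsLayer-class
#' @param object an object.
#' @export
setGeneric("layerName", function(object) standardGeneric("layerName"))

#' @rdname OmicsLayer-class
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname OmicsLayer-class
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))

#' @rdname OmicsLayer-class
#' @export
setGeneric("layerValues", function(object) standardGeneric("layerValues"))

#' @rdname OmicsLayer-class
#' @export
setGeneric("isCompositional", function(object) standardGeneric("isCompositional"))

#' @rdname ModulePartition-class
#' @param object an object.
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname ModulePartition-class
#' @export
setGeneric("moduleColors", function(object) standardGeneric("moduleColors"))

#' @rdname ModulePartition-class
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @rdname EigengeneMatrix-class
#' @param object an object.
#' @export
setGeneric("eigengeneValues", function(object) standardGeneric("eigengeneValues"))

#' @rdname EigengeneMatrix-class
#' @export
setGeneric("moduleIDs", function(object) standardGeneric("moduleIDs"))

#' @rdname OrdinationResult-class
#' @param object an object.
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname OrdinationResult-class
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname OrdinationResult-class
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))

#' @rdname CoInertiaResult-class
#' @param object an object.
#' @export
setGeneric("tableScores", function(object) standardGeneric("tableScores"))

#' @rdname CoInertiaResult-class
#' @export
setGeneric("referenceScores", function(object) standardGeneric("referenceScores"))

#' @rdname CoInertiaResult-class
#' @export
setGeneric("axisCovariances", function(object) standardGeneric("axisCovariances"))

#' @rdname MultiLayerGraph-class
#' @param object an object.
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' @rdname MultiLayerGraph-class
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname AnnotationTable-class
#' @param object an object.
#' @export
setGeneric("annotationData", function(object) standardGeneric("annotationData"))

#' @rdname AnnotationTable-class
#' @export
setGeneric("traitTypes", function(object) standardGeneric("traitTypes"))
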