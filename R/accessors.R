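# Constructors, accessors and show methods for the core classes.

#' Create an OmicsLayer
#'
#' @param values numeric matrix with samples in rows and features in
#'   columns; dimnames are required.
#' @param name layer label.
#' @param compositional logical; mark count/relative-abundance data that
#'   should go through [clrTransform()] before correlation analysis.
#' @return An [OmicsLayer-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("f", 1:4)))
#' omicsLayer(m, "demo")
#' @export
omicsLayer <- function(values, name, compositional = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("OmicsLayer", name = name, values = values,
      compositional = isTRUE(compositional))
}

#' @rdname OmicsLayer-class
#' @export
setMethod("layerName", "OmicsLayer", function(object) object@name)
#' @rdname OmicsLayer-class
#' @export
setMethod("sampleIDs", "OmicsLayer", function(object) rownames(object@values))
#' @rdname OmicsLayer-class
#' @export
setMethod("featureIDs", "OmicsLayer", function(object) colnames(object@values))
#' @rdname OmicsLayer-class
#' @export
setMethod("layerValues", "OmicsLayer", function(object) object@values)
#' @rdname OmicsLayer-class
#' @export
setMethod("isCompositional", "OmicsLayer", function(object) object@compositional)

#' @rdname OmicsLayer-class
#' @export
setMethod("dim", "OmicsLayer", function(x) dim(x@values))

setMethod("show", "OmicsLayer", function(object) {
  cat("OmicsLayer '", object@name, "': ", nrow(object@values), " samples x ",
      ncol(object@values), " features",
      if (object@compositional) " (compositional)", "\n", sep = "")
})

#' Create an AnnotationTable
#'
#' Character columns are converted to factors so that qualitative traits
#' carry explicit levels.
#'
#' @param data data.frame with sample ids as row names.
#' @return An [AnnotationTable-class] object.
#' @export
annotationTable <- function(data) {
  data <- as.data.frame(data)
  chr <- vapply(data, is.character, logical(1))
  data[chr] <- lapply(data[chr], factor)
  new("AnnotationTable", data = data)
}

#' @rdname AnnotationTable-class
#' @export
setMethod("annotationData", "AnnotationTable", function(object) object@data)

#' @rdname AnnotationTable-class
#' @export
setMethod("sampleIDs", "AnnotationTable", function(object) rownames(object@data))

#' @rdname AnnotationTable-class
#' @export
setMethod("traitTypes", "AnnotationTable", function(object) {
  vapply(object@data, function(x)
    if (is.numeric(x)) "quantitative" else "qualitative", character(1))
})

setMethod("show", "AnnotationTable", function(object) {
  tt <- traitTypes(object)
  cat("AnnotationTable: ", nrow(object@data), " samples, ",
      sum(tt == "quantitative"), " quantitative and ",
      sum(tt == "qualitative"), " qualitative traits\n", sep = "")
})

#' Network construction parameters
#'
#' @param correlation feature correlation method.
#' @param networkType adjacency type: \code{"unsigned"} uses |r|^power,
#'   \code{"signed"} uses ((1+r)/2)^power.
#' @param power soft-threshold exponent (default 6, the usual unsigned
#'   fallback when the scale-free fit is inconclusive).
#' @param minModuleSize smallest allowed module.
#' @param cutHeight static cut height as a fraction of the dendrogram's
#'   maximum merge height.
#' @param mergeCut eigengene dissimilarity (1 - r) below which modules are
#'   merged.
#' @return A [NetworkParams-class] object.
#' @export
networkParams <- function(correlation = c("pearson", "spearman"),
                          networkType = c("unsigned", "signed"),
                          power = 6, minModuleSize = 20,
                          cutHeight = 0.99, mergeCut = 0.25) {
  new("NetworkParams",
      correlation = match.arg(correlation),
      networkType = match.arg(networkType),
      power = power, minModuleSize = minModuleSize,
      cutHeight = cutHeight, mergeCut = mergeCut)
}

setMethod("show", "NetworkParams", function(object) {
  cat("NetworkParams: ", object@networkType, " ", object@correlation,
      " network, power = ", object@power,
      ", minModuleSize = ", object@minModuleSize,
      ", cutHeight = ", object@cutHeight,
      ", mergeCut = ", object@mergeCut, "\n", sep = "")
})

#' @rdname ModulePartition-class
#' @export
setMethod("featureIDs", "ModulePartition", function(object) object@featureIDs)
#' @rdname ModulePartition-class
#' @export
setMethod("moduleLabels", "ModulePartition", function(object)
  stats::setNames(object@labels, object@featureIDs))
#' @rdname ModulePartition-class
#' @export
setMethod("moduleColors", "ModulePartition", function(object)
  stats::setNames(object@colors, object@featureIDs))
#' @rdname ModulePartition-class
#' @export
setMethod("moduleSizes", "ModulePartition", function(object) {
  tab <- table(factor(object@labels[object@labels > 0]))
  stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "ModulePartition", function(object) {
  k <- sum(unique(object@labels) > 0)
  cat("ModulePartition: ", length(object@featureIDs), " features in ", k,
      " modules (", sum(object@labels == 0L), " unassigned)\n", sep = "")
})

#' @rdname EigengeneMatrix-class
#' @export
setMethod("eigengeneValues", "EigengeneMatrix", function(object) object@values)
#' @rdname EigengeneMatrix-class
#' @export
setMethod("moduleIDs", "EigengeneMatrix", function(object) object@moduleIDs)
#' @rdname EigengeneMatrix-class
#' @export
setMethod("sampleIDs", "EigengeneMatrix", function(object) rownames(object@values))

setMethod("show", "EigengeneMatrix", function(object) {
  cat("EigengeneMatrix: ", nrow(object@values), " samples x ",
      ncol(object@values), " module eigengenes\n", sep = "")
})

#' @rdname OrdinationResult-class
#' @export
setMethod("scores", "OrdinationResult", function(object) object@coordinates)
#' @rdname OrdinationResult-class
#' @export
setMethod("eigenvalues", "OrdinationResult", function(object) object@eigenvalues)
#' @rdname OrdinationResult-class
#' @export
setMethod("explainedVariance", "OrdinationResult", function(object) object@explained)

setMethod("show", "OrdinationResult", function(object) {
  cat(toupper(object@method), " ordination: ", nrow(object@coordinates),
      " samples, ", ncol(object@coordinates), " axes (",
      paste0(round(100 * object@explained[seq_len(min(3, length(object@explained)))], 1),
             "%", collapse = ", "),
      if (length(object@explained) > 3) ", ...", ")\n", sep = "")
})

#' @rdname CoInertiaResult-class
#' @export
setMethod("tableScores", "CoInertiaResult", function(object) object@tableScores)
#' @rdname CoInertiaResult-class
#' @export
setMethod("referenceScores", "CoInertiaResult", function(object) object@reference)
#' @rdname CoInertiaResult-class
#' @export
setMethod("axisCovariances", "CoInertiaResult", function(object) object@covariances)

setMethod("show", "CoInertiaResult", function(object) {
  cat(if (object@method == "mcia") "Multiple co-inertia" else "Co-inertia",
      ": ", length(object@tableScores), " tables, ",
      length(object@covariances), " axes; axis covariances: ",
      paste(signif(object@covariances, 4), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ProcrustesResult", function(object) {
  cat("Procrustes superposition: m2 = ", signif(object@m2, 6), sep = "")
  if (!is.na(object@permutationP))
    cat(", permutation p = ", signif(object@permutationP, 4),
        " (", object@nPermutations, " permutations)", sep = "")
  cat("\n")
})

#' @rdname MultiLayerGraph-class
#' @export
setMethod("graphNodes", "MultiLayerGraph", function(object) object@nodes)
#' @rdname MultiLayerGraph-class
#' @export
setMethod("graphEdges", "MultiLayerGraph", function(object) object@edges)

setMethod("show", "MultiLayerGraph", function(object) {
  cat("MultiLayerGraph anchored on '", object@anchorTrait, "': ",
      nrow(object@nodes), " module nodes, ", nrow(object@edges),
      " inter-layer edges at BH alpha = ", object@alpha, "\n", sep = "")
})

setMethod("show", "OplsModel", function(object) {
  cat("OPLS model: 1 predictive + ", ncol(object@orthoScores),
      " orthogonal component(s), ", length(object@featureIDs),
      " features, R2Y = ", signif(object@R2Y, 4),
      " (", object@yEncoding, " response)\n", sep = "")
})
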