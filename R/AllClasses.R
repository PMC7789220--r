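#' @import methods
NULL

#' OmicsLayer: one omics table on a common sample set
#'
#' Container for a single omics layer: a numeric samples-by-features matrix
#' with a layer name and a flag marking compositional (relative count) data
#' such as OTU/ASV tables. Samples are always stored in rows.
#'
#' @slot name single character label for the layer.
#' @slot values numeric matrix, samples in rows, features in columns, with
#'   unique non-empty dimnames.
#' @slot compositional logical flag; \code{TRUE} for count/relative data
#'   that should be centered-log-ratio transformed before correlation
#'   analysis.
#'
#' @seealso [omicsLayer()], [clrTransform()], [prevalenceFilter()]
#' @export
setClass("OmicsLayer",
  slots = c(name = "character", values = "matrix", compositional = "logical"))

setValidity("OmicsLayer", function(object) {
  v <- object@values
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have sample row names and feature column names")
  else {
    if (anyDuplicated(rownames(v)) || any(!nzchar(rownames(v))))
      msg <- c(msg, "sample ids must be unique and non-empty")
    if (anyDuplicated(colnames(v)) || any(!nzchar(colnames(v))))
      msg <- c(msg, "feature ids must be unique and non-empty")
  }
  if (is.numeric(v) && any(!is.finite(v)))
    msg <- c(msg, "all values must be finite")
  if (length(msg)) msg else TRUE
})

#' AnnotationTable: per-sample contextual parameters
#'
#' Holds the annotation table describing external parameters (traits) for
#' each sample. Numeric columns are treated as quantitative traits; factor
#' or character columns as qualitative traits.
#'
#' @slot data data.frame with sample ids as row names; each column is one
#'   trait.
#' @export
setClass("AnnotationTable", slots = c(data = "data.frame"))

setValidity("AnnotationTable", function(object) {
  d <- object@data
  msg <- character()
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msg <- c(msg, "sample ids (row names) must be present and unique")
  ok <- vapply(d, function(x)
    is.numeric(x) || is.factor(x) || is.character(x) || is.logical(x),
    logical(1))
  if (!all(ok))
    msg <- c(msg, paste("unsupported column type in:",
                        paste(names(d)[!ok], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' DistanceMatrix: pairwise sample distances
#'
#' @slot values symmetric nonnegative matrix with zero diagonal and sample
#'   ids as dimnames.
#' @slot metric name of the distance used.
#' @export
setClass("DistanceMatrix", slots = c(values = "matrix", metric = "character"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "distance matrix must be square")
  else {
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric within 1e-12")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be exactly zero")
    if (any(v < 0)) msg <- c(msg, "distances must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' OrdinationResult: sample coordinates from PCA or PCoA
#'
#' @slot coordinates samples-by-axes score matrix.
#' @slot eigenvalues nonincreasing eigenvalues (PCoA may include negative
#'   trailing values, reported for diagnostics).
#' @slot explained fraction of variance explained per retained axis,
#'   computed over the positive part of the spectrum.
#' @slot loadings features-by-axes matrix (PCA only; 0-row otherwise).
#' @slot method "pca" or "pcoa".
#' @export
setClass("OrdinationResult",
  slots = c(coordinates = "matrix", eigenvalues = "numeric",
            explained = "numeric", loadings = "matrix", method = "character"))

setValidity("OrdinationResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) > 1 && any(diff(ev) > 1e-8 * max(abs(ev), 1)))
    msg <- c(msg, "eigenvalues must be nonincreasing")
  if (length(object@explained) &&
      (any(object@explained < -1e-12) || sum(object@explained) > 1 + 1e-8))
    msg <- c(msg, "explained fractions must lie in [0,1] and sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' CoInertiaResult: covariance-maximizing axes across tables
#'
#' Result of pairwise co-inertia or multiple co-inertia. Per-table sample
#' scores share one sample order; \code{covariances} holds the per-axis
#' mean pairwise covariance between table scores (for two tables this is
#' the co-inertia singular value divided by n).
#'
#' @slot tableScores named list of samples-by-axes score matrices, one per
#'   table.
#' @slot reference samples-by-axes consensus (synthetic) scores.
#' @slot covariances per-axis mean pairwise covariance, nonincreasing.
#' @slot loadings named list of features-by-axes weight matrices.
#' @slot method "coinertia" or "mcia".
#' @export
setClass("CoInertiaResult",
  slots = c(tableScores = "list", reference = "matrix",
            covariances = "numeric", loadings = "list", method = "character"))

setValidity("CoInertiaResult", function(object) {
  msg <- character()
  cv <- object@covariances
  if (any(cv < -1e-10)) msg <- c(msg, "covariances must be nonnegative")
  if (length(cv) > 1 && any(diff(cv) > 1e-8 * max(cv, 1e-300)))
    msg <- c(msg, "covariances must be nonincreasing")
  rn <- lapply(object@tableScores, rownames)
  if (length(rn) > 1 && !all(vapply(rn[-1], identical, logical(1), rn[[1]])))
    msg <- c(msg, "per-table scores must share one sample order")
  if (length(msg)) msg else TRUE
})

#' ProcrustesResult: optimal superposition of two ordinations
#'
#' @slot m2 symmetric Procrustes statistic in [0,1]; 0 means identical
#'   shapes after translation, scaling and rotation.
#' @slot rotation orthogonal matrix mapping the second configuration onto
#'   the first.
#' @slot scale positive scaling factor applied to the second configuration.
#' @slot translation translation vector.
#' @slot permutationP permutation p-value (PROTEST); NA when no
#'   permutations were requested.
#' @slot nPermutations number of permutations used.
#' @slot seed RNG seed used for the permutations.
#' @export
setClass("ProcrustesResult",
  slots = c(m2 = "numeric", rotation = "matrix", scale = "numeric",
            translation = "numeric", permutationP = "numeric",
            nPermutations = "numeric", seed = "numeric"))

setValidity("ProcrustesResult", function(object) {
  msg <- character()
  if (object@m2 < -1e-10 || object@m2 > 1 + 1e-10)
    msg <- c(msg, "m2 must lie in [0,1]")
  p <- object@permutationP
  if (!is.na(p) && (p <= 0 || p > 1))
    msg <- c(msg, "permutation p must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' NetworkParams: settings for weighted correlation network construction
#'
#' @slot correlation "pearson" or "spearman".
#' @slot networkType "unsigned" (|r|^beta) or "signed" (((1+r)/2)^beta).
#' @slot power soft-threshold exponent beta, at least 1.
#' @slot minModuleSize smallest feature count for a proper module.
#' @slot cutHeight static tree-cut height, as a fraction of the
#'   dendrogram's maximum merge height, in (0,1].
#' @slot mergeCut eigengene dissimilarity below which modules are merged.
#' @export
setClass("NetworkParams",
  slots = c(correlation = "character", networkType = "character",
            power = "numeric", minModuleSize = "numeric",
            cutHeight = "numeric", mergeCut = "numeric"))

setValidity("NetworkParams", function(object) {
  msg <- character()
  if (!object@correlation %in% c("pearson", "spearman"))
    msg <- c(msg, "correlation must be 'pearson' or 'spearman'")
  if (!object@networkType %in% c("unsigned", "signed"))
    msg <- c(msg, "networkType must be 'unsigned' or 'signed'")
  if (object@power < 1) msg <- c(msg, "power must be >= 1")
  if (object@minModuleSize < 2) msg <- c(msg, "minModuleSize must be >= 2")
  if (object@cutHeight <= 0 || object@cutHeight > 1)
    msg <- c(msg, "cutHeight must lie in (0,1]")
  if (object@mergeCut < 0 || object@mergeCut >= 1)
    msg <- c(msg, "mergeCut must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' ModulePartition: module labels per feature
#'
#' Label 0 marks unassigned features (displayed grey, following the usual
#' co-expression network convention); proper modules are numbered 1..K by
#' decreasing size.
#'
#' @slot featureIDs feature identifiers.
#' @slot labels integer module label per feature; 0 = unassigned.
#' @slot colors display color name per feature, "grey" reserved for 0.
#' @slot minModuleSize the minimum size used when the partition was built.
#' @export
setClass("ModulePartition",
  slots = c(featureIDs = "character", labels = "integer",
            colors = "character", minModuleSize = "numeric"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@featureIDs) ||
      length(object@colors) != length(object@featureIDs))
    msg <- c(msg, "featureIDs, labels and colors must have equal length")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
  tab <- table(object@labels[object@labels > 0])
  if (length(tab) && any(tab < object@minModuleSize))
    msg <- c(msg, "every proper module must have at least minModuleSize members")
  if (any((object@labels == 0L) != (object@colors == "grey")))
    msg <- c(msg, "'grey' must be used exactly for label 0")
  if (length(msg)) msg else TRUE
})

#' EigengeneMatrix: one representative profile per module
#'
#' Each column is a module eigengene: the first left singular vector of the
#' module's standardized sample-by-feature submatrix, scaled to unit
#' variance and oriented to correlate nonnegatively with the module's mean
#' standardized profile.
#'
#' @slot values samples-by-modules matrix; columns named \code{ME<id>}.
#' @slot moduleIDs integer module ids in column order.
#' @export
setClass("EigengeneMatrix",
  slots = c(values = "matrix", moduleIDs = "integer"))

setValidity("EigengeneMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@moduleIDs))
    msg <- c(msg, "one module id per column required")
  if (ncol(object@values)) {
    sds <- apply(object@values, 2, stats::sd)
    if (any(abs(sds - 1) > 1e-6))
      msg <- c(msg, "eigengene columns must have unit variance")
  }
  if (length(msg)) msg else TRUE
})

#' MultiLayerGraph: trait-anchored multilayer module network
#'
#' Nodes are (layer, module) pairs annotated with their correlation to the
#' anchor trait; edges are inter-layer module pairs whose eigengene
#' correlation survives Benjamini-Hochberg control at \code{alpha}.
#'
#' @slot nodes data.frame with columns layer, module, size, trait_r,
#'   trait_q.
#' @slot edges data.frame with columns layer_a, module_a, layer_b,
#'   module_b, r, p, q.
#' @slot anchorTrait name of the anchoring contextual parameter.
#' @slot alpha BH significance level used to retain edges.
#' @export
setClass("MultiLayerGraph",
  slots = c(nodes = "data.frame", edges = "data.frame",
            anchorTrait = "character", alpha = "numeric"))

setValidity("MultiLayerGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$layer_a == e$layer_b)) msg <- c(msg, "within-layer edges are not allowed")
    if (any(abs(e$r) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
    if (any(e$q + 1e-12 < e$p)) msg <- c(msg, "q must be >= p")
  }
  n <- object@nodes
  if (nrow(n) && anyDuplicated(n[, c("layer", "module")]))
    msg <- c(msg, "(layer, module) node keys must be unique")
  if (length(msg)) msg else TRUE
})

#' OplsModel: orthogonal partial least squares fit
#'
#' One predictive component plus \code{nOrth} Y-orthogonal components
#' (orthogonal-signal-corrected NIPALS). Qualitative responses are
#' dummy-coded; quantitative responses standardized.
#'
#' @slot scores predictive score vector (one column).
#' @slot loadings predictive loading vector.
#' @slot weights predictive weight vector (unit norm).
#' @slot yWeights response weights of the predictive component.
#' @slot orthoScores,orthoLoadings,orthoWeights orthogonal-component
#'   matrices (0 columns when nOrth = 0).
#' @slot R2Y fraction of response variance explained.
#' @slot yEncoding "numeric" or "dummy".
#' @slot featureIDs predictor names.
#' @slot traitR per-feature correlation to the (max-|r| column of the)
#'   response.
#' @export
setClass("OplsModel",
  slots = c(scores = "matrix", loadings = "matrix", weights = "matrix",
            yWeights = "matrix", orthoScores = "matrix",
            orthoLoadings = "matrix", orthoWeights = "matrix",
            R2Y = "numeric", yEncoding = "character",
            featureIDs = "character", traitR = "numeric"))

setValidity("OplsModel", function(object) {
  msg <- character()
  if (object@R2Y < -1e-10 || object@R2Y > 1 + 1e-10)
    msg <- c(msg, "R2Y must lie in [0,1]")
  if (ncol(object@orthoScores)) {
    cp <- crossprod(object@scores, object@orthoScores)
    nn <- sqrt(sum(object@scores^2)) *
      sqrt(colSums(object@orthoScores^2))
    if (any(abs(cp) > 1e-8 * pmax(nn, 1e-300)))
      msg <- c(msg, "predictive and orthogonal scores must be orthogonal")
  }
  if (length(msg)) msg else TRUE
})
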