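# Loading, alignment, filtering and transformation of omics tables.

.readDelim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

#' Read one omics table from delimited text
#'
#' Reads a TSV/CSV file whose first column holds identifiers and returns an
#' [OmicsLayer-class] with samples in rows regardless of the on-disk
#' orientation. Non-numeric cells and duplicated identifiers are rejected
#' with informative errors.
#'
#' @param path path to a delimited text file with a header row and an id
#'   column first.
#' @param orientation whether samples are in rows or in columns on disk.
#' @param name layer label.
#' @param compositional mark the layer as compositional counts.
#' @param sep field separator; guessed from the file extension when NULL.
#' @return An [OmicsLayer-class].
#' @export
readLayer <- function(path,
                      orientation = c("samples_in_rows", "samples_in_columns"),
                      name = sub("\\.[^.]*$", "", basename(path)),
                      compositional = FALSE, sep = NULL) {
  orientation <- match.arg(orientation)
  d <- .readDelim(path, sep)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicated ", if (orientation == "samples_in_rows") "sample" else "feature",
         " id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  d <- d[, -1, drop = FALSE]
  for (j in seq_along(d)) {
    x <- d[[j]]
    if (!is.numeric(x)) {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xn) & !is.na(x))
      if (length(bad))
        stop("non-numeric value in column '", names(d)[j], "', row '",
             ids[bad[1]], "' of ", path)
      d[[j]] <- xn
    }
  }
  if (anyDuplicated(names(d)))
    stop("duplicated ", if (orientation == "samples_in_rows") "feature" else "sample",
         " id(s) in header of ", path)
  m <- as.matrix(d)
  rownames(m) <- ids
  if (orientation == "samples_in_columns") m <- t(m)
  omicsLayer(m, name = name, compositional = compositional)
}

#' Read a sample annotation table
#'
#' @param path delimited text file, first column = sample ids; remaining
#'   columns are quantitative (numeric) or qualitative traits.
#' @param sep field separator; guessed from the extension when NULL.
#' @return An [AnnotationTable-class].
#' @export
readAnnotation <- function(path, sep = NULL) {
  d <- .readDelim(path, sep)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample id(s) in ", path)
  d <- d[, -1, drop = FALSE]
  rownames(d) <- ids
  annotationTable(d)
}

#' Read a feature taxonomy table
#'
#' @param path delimited text file, first column = feature ids, remaining
#'   columns = taxonomic ranks in order (e.g. Phylum ... Species). Empty
#'   cells and NA are treated as missing assignments.
#' @param sep field separator; guessed from the extension when NULL.
#' @return data.frame with feature ids as row names and one column per
#'   rank.
#' @export
readTaxonomy <- function(path, sep = NULL) {
  d <- .readDelim(path, sep)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) stop("duplicated feature id(s) in ", path)
  d <- d[, -1, drop = FALSE]
  d[] <- lapply(d, as.character)
  rownames(d) <- ids
  d
}

#' Restrict layers and annotation to their common samples
#'
#' All layers and the annotation table are subset to the intersection of
#' their sample ids, in the order of the first layer, so every downstream
#' analysis sees one canonical sample order.
#'
#' @param layers list of [OmicsLayer-class] objects (at least one).
#' @param annotation optional [AnnotationTable-class].
#' @return list with elements \code{layers}, \code{annotation} and
#'   \code{dropped} (named list of sample ids removed from each input).
#' @export
alignSamples <- function(layers, annotation = NULL) {
  if (is(layers, "OmicsLayer")) layers <- list(layers)
  if (!length(layers)) stop("at least one layer is required")
  idsets <- lapply(layers, sampleIDs)
  if (!is.null(annotation)) idsets <- c(idsets, list(sampleIDs(annotation)))
  common <- Reduce(intersect, idsets)
  if (!length(common))
    stop("no samples are shared by all inputs; check sample ids")
  common <- idsets[[1]][idsets[[1]] %in% common]  # canonical order
  dropped <- lapply(idsets, function(x) setdiff(x, common))
  nms <- vapply(layers, layerName, character(1))
  names(dropped) <- c(nms, if (!is.null(annotation)) "annotation")
  outLayers <- lapply(layers, function(l)
    omicsLayer(layerValues(l)[common, , drop = FALSE], layerName(l),
               isCompositional(l)))
  names(outLayers) <- nms
  outAnn <- if (is.null(annotation)) NULL else
    annotationTable(annotationData(annotation)[common, , drop = FALSE])
  list(layers = outLayers, annotation = outAnn, dropped = dropped)
}

#' Filter features by prevalence
#'
#' Keeps features present (value strictly greater than zero) in at least
#' \code{minPrevalence} of the samples; ties at the threshold are kept.
#'
#' @param layer an [OmicsLayer-class].
#' @param minPrevalence required fraction of samples with a nonzero value,
#'   in [0,1].
#' @return The filtered [OmicsLayer-class]; feature order preserved.
#' @export
prevalenceFilter <- function(layer, minPrevalence) {
  stopifnot(minPrevalence >= 0, minPrevalence <= 1)
  v <- layerValues(layer)
  prev <- colMeans(v > 0)
  keep <- prev >= minPrevalence
  if (!any(keep))
    stop("prevalence filter at ", minPrevalence,
         " removed every feature; lower the threshold")
  omicsLayer(v[, keep, drop = FALSE], layerName(layer), isCompositional(layer))
}

.defaultPseudocount <- function(v) {
  # counts get +1; real-valued compositional tables get half the smallest
  # positive entry
  if (all(v == round(v))) 1 else min(v[v > 0]) / 2
}

#' Centered log-ratio transform
#'
#' For each sample i and feature j, clr_ij = ln(x_ij + delta) - mean_j
#' ln(x_ij + delta), removing the arbitrary scale of compositional
#' sequencing counts. Every output row sums to zero.
#'
#' @param layer an [OmicsLayer-class] with nonnegative values.
#' @param pseudocount delta added before taking logs. Default: 1 for
#'   integer counts, half the minimum positive value otherwise. May be 0
#'   when all values are strictly positive.
#' @return The transformed [OmicsLayer-class] with the compositional flag
#'   cleared.
#' @export
clrTransform <- function(layer, pseudocount = NULL) {
  v <- layerValues(layer)
  if (any(v < 0)) stop("clrTransform requires nonnegative values")
  if (is.null(pseudocount)) pseudocount <- .defaultPseudocount(v)
  if (pseudocount == 0 && any(v == 0))
    stop("zero values need a positive pseudocount")
  lg <- log(v + pseudocount)
  out <- lg - rowMeans(lg)
  omicsLayer(out, layerName(layer), compositional = FALSE)
}

#' Transform a layer
#'
#' One dispatch over the common normalizations: centered log-ratio
#' (\code{"clr"}), \code{"log2"} (log2(x+1)), total-sum scaling
#' (\code{"tss"}, each row divided by its sum) and per-feature
#' unit-variance standardization (\code{"standardize"}).
#'
#' @param layer an [OmicsLayer-class].
#' @param method transformation name.
#' @param ... passed to [clrTransform()] (e.g. \code{pseudocount}).
#' @return The transformed [OmicsLayer-class].
#' @export
transformLayer <- function(layer,
                           method = c("clr", "log2", "tss", "standardize"),
                           ...) {
  method <- match.arg(method)
  v <- layerValues(layer)
  switch(method,
    clr = clrTransform(layer, ...),
    log2 = {
      if (any(v < 0)) stop("log2 transform requires nonnegative values")
      omicsLayer(log2(v + 1), layerName(layer), isCompositional(layer))
    },
    tss = {
      if (any(v < 0)) stop("total-sum scaling requires nonnegative values")
      rs <- rowSums(v)
      if (any(rs == 0)) stop("total-sum scaling: sample(s) with zero total: ",
                             paste(rownames(v)[rs == 0], collapse = ", "))
      omicsLayer(v / rs, layerName(layer), isCompositional(layer))
    },
    standardize = {
      sds <- apply(v, 2, stats::sd)
      if (any(sds == 0))
        stop("zero-variance feature(s): ",
             paste(colnames(v)[sds == 0], collapse = ", "))
      omicsLayer(scale(v), layerName(layer), compositional = FALSE)
    })
}

#' Flag outlier samples by standardized network connectivity
#'
#' Builds a sample-sample affinity network, a_ij = ((1 + cor(x_i, x_j))/2)^2,
#' computes each sample's connectivity k_i = sum_{j != i} a_ij, standardizes
#' the connectivities and flags samples with z below \code{zCut}. Flagged
#' samples are reported only; removal is left to the user.
#'
#' @param layer an [OmicsLayer-class] with at least 3 samples.
#' @param zCut standardized-connectivity cutoff (default -2.5).
#' @return data.frame with columns sample, connectivity, z and flagged;
#'   one row per sample, in sample order.
#' @export
detectOutliers <- function(layer, zCut = -2.5) {
  v <- layerValues(layer)
  if (nrow(v) < 3) stop("outlier detection needs at least 3 samples")
  a <- ((1 + stats::cor(t(v))) / 2)^2
  k <- rowSums(a) - diag(a)
  z <- (k - mean(k)) / stats::sd(k)
  data.frame(sample = rownames(v), connectivity = k, z = z,
             flagged = z < zCut, row.names = NULL)
}

#' Drop samples from a layer
#'
#' Convenience companion of [detectOutliers()].
#'
#' @param layer an [OmicsLayer-class].
#' @param samples sample ids to remove.
#' @return The reduced [OmicsLayer-class].
#' @export
removeSamples <- function(layer, samples) {
  v <- layerValues(layer)
  keep <- setdiff(rownames(v), samples)
  if (!length(keep)) stop("removing these samples would empty the layer")
  omicsLayer(v[keep, , drop = FALSE], layerName(layer), isCompositional(layer))
}

#' Relative abundance at a taxonomic rank
#'
#' Sums counts of features sharing a lineage at the requested rank
#' (missing assignments are pooled under "Unclassified") and divides each
#' sample by its total, so rows lie on the simplex; all-zero samples stay
#' all-zero.
#'
#' @param layer an [OmicsLayer-class] of nonnegative counts.
#' @param taxonomy data.frame from [readTaxonomy()]: feature ids as row
#'   names, one column per rank.
#' @param rank rank name, one of \code{colnames(taxonomy)}.
#' @return samples-by-taxa matrix of fractions.
#' @export
relativeAbundance <- function(layer, taxonomy, rank) {
  v <- layerValues(layer)
  if (any(v < 0)) stop("relative abundance requires nonnegative counts")
  if (!rank %in% colnames(taxonomy))
    stop("unknown rank '", rank, "'; available: ",
         paste(colnames(taxonomy), collapse = ", "))
  tax <- taxonomy[match(colnames(v), rownames(taxonomy)), rank]
  tax[is.na(tax) | !nzchar(tax)] <- "Unclassified"
  groups <- unique(tax)
  agg <- sapply(groups, function(g)
    rowSums(v[, tax == g, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(v),
                dimnames = list(rownames(v), groups))
  tot <- rowSums(agg)
  nz <- tot > 0
  agg[nz, ] <- agg[nz, , drop = FALSE] / tot[nz]
  agg
}
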