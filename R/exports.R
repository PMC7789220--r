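# Plain-text exports of analysis results (TSV mirrors of the CSV/network
# downloads a user would take away).

.writeTSV <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an omics layer as TSV (samples in rows)
#'
#' @param layer an [OmicsLayer-class].
#' @param path output file.
#' @export
writeLayer <- function(layer, path) {
  v <- layerValues(layer)
  d <- data.frame(sample = rownames(v), v, check.names = FALSE)
  .writeTSV(d, path)
}

#' Export the per-layer network results
#'
#' Writes the module assignment table (feature, module, color, kME to its
#' own module), the eigengene matrix, the module-trait report and, when
#' given, the soft-threshold report.
#'
#' @param dir output directory (created if missing).
#' @param prefix file name prefix, typically the layer name.
#' @param partition a [ModulePartition-class].
#' @param eigengenes an [EigengeneMatrix-class].
#' @param kme features-by-modules matrix from [moduleMembership()].
#' @param traitReport data.frame from [moduleTraitCorrelation()]
#'   (optional).
#' @param softThreshold list from [pickSoftThreshold()] (optional).
#' @return the directory, invisibly.
#' @export
exportNetworkTables <- function(dir, prefix, partition, eigengenes,
                                kme = NULL, traitReport = NULL,
                                softThreshold = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  own <- rep(NA_real_, length(partition@featureIDs))
  if (!is.null(kme)) {
    col <- match(paste0("ME", partition@labels), colnames(kme))
    own <- ifelse(is.na(col), NA_real_,
                  kme[cbind(seq_along(col), col)])
  }
  .writeTSV(data.frame(feature = partition@featureIDs,
                       module = partition@labels,
                       color = partition@colors, kME = own),
            file.path(dir, paste0(prefix, "_modules.tsv")))
  em <- eigengeneValues(eigengenes)
  .writeTSV(data.frame(sample = rownames(em), em, check.names = FALSE),
            file.path(dir, paste0(prefix, "_eigengenes.tsv")))
  if (!is.null(traitReport))
    .writeTSV(traitReport, file.path(dir, paste0(prefix, "_module_trait.tsv")))
  if (!is.null(softThreshold))
    .writeTSV(softThreshold$report,
              file.path(dir, paste0(prefix, "_soft_threshold.tsv")))
  invisible(dir)
}

#' Export a weighted edge list above a cutoff
#'
#' @param mat symmetric weight matrix (adjacency or TOM) with feature
#'   dimnames.
#' @param path output file.
#' @param cutoff minimum weight (strict) for an edge to be written.
#' @return the path, invisibly.
#' @export
exportEdgeList <- function(mat, path, cutoff = 0.1) {
  ut <- which(upper.tri(mat) & mat > cutoff, arr.ind = TRUE)
  .writeTSV(data.frame(feature_a = rownames(mat)[ut[, 1]],
                       feature_b = colnames(mat)[ut[, 2]],
                       weight = mat[ut]),
            path)
}

#' Export an ordination or co-inertia result
#'
#' Writes sample coordinates and eigenvalues; for co-inertia results also
#' the per-table triangle-vertex coordinates and the top drivers per
#' table and axis.
#'
#' @param res an [OrdinationResult-class] or [CoInertiaResult-class].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param topN drivers per table and axis for co-inertia results.
#' @return the directory, invisibly.
#' @export
exportOrdination <- function(res, dir, prefix, topN = 25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is(res, "OrdinationResult")) {
    co <- scores(res)
    .writeTSV(data.frame(sample = rownames(co), co, check.names = FALSE),
              file.path(dir, paste0(prefix, "_coordinates.tsv")))
    .writeTSV(data.frame(axis = seq_along(eigenvalues(res)),
                         eigenvalue = eigenvalues(res)),
              file.path(dir, paste0(prefix, "_eigenvalues.tsv")))
  } else {
    .writeTSV(triangleVertices(res),
              file.path(dir, paste0(prefix, "_vertices.tsv")))
    drv <- do.call(rbind, lapply(names(res@loadings), function(ly)
      do.call(rbind, lapply(seq_along(res@covariances), function(ax) {
        d <- extractDrivers(res, ly, ax, topN)
        cbind(layer = ly, axis = ax, d)
      }))))
    .writeTSV(drv, file.path(dir, paste0(prefix, "_drivers.tsv")))
    .writeTSV(data.frame(axis = seq_along(res@covariances),
                         covariance = res@covariances),
              file.path(dir, paste0(prefix, "_covariances.tsv")))
  }
  invisible(dir)
}

#' Export the multilayer integration tables
#'
#' Writes the retained inter-layer edge table, the hive layout and,
#' optionally, a bipartite feature network with its cross-correlation
#' matrix.
#'
#' @param dir output directory.
#' @param graph a [MultiLayerGraph-class].
#' @param bipartite optional result of [bipartiteFeatureNetwork()].
#' @return the directory, invisibly.
#' @export
exportMultilayerTables <- function(dir, graph, bipartite = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTSV(graphEdges(graph), file.path(dir, "multilayer_edges.tsv"))
  .writeTSV(graphNodes(graph), file.path(dir, "multilayer_nodes.tsv"))
  if (nrow(graphNodes(graph)))
    .writeTSV(hiveLayout(graph), file.path(dir, "hive_layout.tsv"))
  exportGraphML(graph, file.path(dir, "multilayer_graph.graphml"))
  if (!is.null(bipartite)) {
    .writeTSV(bipartite$edges, file.path(dir, "bipartite_edges.tsv"))
    m <- bipartite$matrix
    .writeTSV(data.frame(feature = rownames(m), m, check.names = FALSE),
              file.path(dir, "bipartite_correlations.tsv"))
  }
  invisible(dir)
}
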