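# Multi-layer integration: eigengene cross-correlation, the
# trait-anchored multilayer module graph, hive layout and module-pair
# bipartite feature networks.

#' Correlate module eigengenes across omics layers
#'
#' The core of the multi-layer integration strategy: every module of every
#' layer is associated with every module of every other layer by directly
#' correlating their eigengenes. Because each layer is first reduced to a
#' handful of eigengenes, the number of tests stays small, which preserves
#' statistical power. P-values come from the t distribution with n - 2
#' degrees of freedom; Benjamini-Hochberg adjustment is applied jointly
#' over all inter-layer module pairs.
#'
#' @param eigengeneSets named list (one [EigengeneMatrix-class] per layer,
#'   at least two) with identical sample order.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame of edge candidates: layer_a, module_a, layer_b,
#'   module_b, r, p, q.
#' @export
eigengeneCrossCorrelation <- function(eigengeneSets,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(eigengeneSets) < 2)
    stop("need eigengenes from at least 2 layers")
  nms <- names(eigengeneSets)
  if (is.null(nms) || any(!nzchar(nms))) stop("eigengeneSets must be named")
  rn <- lapply(eigengeneSets, sampleIDs)
  if (!all(vapply(rn[-1], identical, logical(1), rn[[1]])))
    stop("all eigengene sets must share the same samples in the same order")
  n <- length(rn[[1]])
  if (n < 3) stop("need at least 3 shared samples")
  out <- list()
  for (i in seq_len(length(eigengeneSets) - 1)) {
    for (j in (i + 1):length(eigengeneSets)) {
      ct <- .corTestGrid(eigengeneValues(eigengeneSets[[i]]),
                         eigengeneValues(eigengeneSets[[j]]), method)
      g <- expand.grid(module_a = moduleIDs(eigengeneSets[[i]]),
                       module_b = moduleIDs(eigengeneSets[[j]]))
      out[[length(out) + 1L]] <- data.frame(
        layer_a = nms[i], module_a = g$module_a,
        layer_b = nms[j], module_b = g$module_b,
        r = as.vector(ct$r), p = as.vector(ct$p))
    }
  }
  edges <- do.call(rbind, out)
  edges$q <- NA_real_
  ok <- !is.na(edges$p)
  edges$q[ok] <- stats::p.adjust(edges$p[ok], method = "BH")
  edges
}

.anchorAssociation <- function(traitReport, anchorTrait) {
  # per module: the anchor trait's r/q; for qualitative anchors, the
  # indicator column with the largest |r|
  sub <- traitReport[traitReport$trait == anchorTrait, , drop = FALSE]
  if (!nrow(sub)) stop("trait '", anchorTrait, "' absent from a trait report")
  do.call(rbind, lapply(split(sub, sub$module), function(s) {
    i <- which.max(abs(s$r))
    data.frame(module = s$module[i], trait_r = s$r[i], trait_q = s$q[i],
               column = s$column[i])
  }))
}

#' Build the trait-anchored multilayer module graph
#'
#' Keeps the inter-layer eigengene edges with q at or below \code{alpha}
#' and annotates every module node with its correlation to the anchoring
#' trait. Nodes with neither a retained edge nor a significant trait
#' association are dropped (modules with no significant association are
#' not depicted).
#'
#' @param edges edge candidates from [eigengeneCrossCorrelation()].
#' @param traitReports named list of data.frames from
#'   [moduleTraitCorrelation()], one per layer.
#' @param anchorTrait trait used to anchor the graph; for a qualitative
#'   trait each module reports its max-|r| level.
#' @param alpha BH significance level (default 0.05).
#' @param partitions optional named list of [ModulePartition-class]
#'   objects used to record module sizes.
#' @return A [MultiLayerGraph-class].
#' @export
buildMultiLayerGraph <- function(edges, traitReports, anchorTrait,
                                 alpha = 0.05, partitions = NULL) {
  layers <- union(edges$layer_a, edges$layer_b)
  if (!all(layers %in% names(traitReports)))
    stop("traitReports must contain every layer present in the edges")
  keptEdges <- edges[!is.na(edges$q) & edges$q <= alpha, , drop = FALSE]
  nodes <- do.call(rbind, lapply(layers, function(ly) {
    an <- .anchorAssociation(traitReports[[ly]], anchorTrait)
    size <- NA_integer_
    if (!is.null(partitions) && ly %in% names(partitions)) {
      sz <- moduleSizes(partitions[[ly]])
      size <- as.integer(sz[as.character(an$module)])
    }
    data.frame(layer = ly, module = an$module, size = size,
               trait_r = an$trait_r, trait_q = an$trait_q,
               anchor_column = an$column, row.names = NULL)
  }))
  inEdge <- paste(nodes$layer, nodes$module) %in%
    c(paste(keptEdges$layer_a, keptEdges$module_a),
      paste(keptEdges$layer_b, keptEdges$module_b))
  traitSig <- !is.na(nodes$trait_q) & nodes$trait_q <= alpha
  nodes <- nodes[inEdge | traitSig, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(keptEdges) <- NULL
  new("MultiLayerGraph", nodes = nodes, edges = keptEdges,
      anchorTrait = anchorTrait, alpha = alpha)
}

#' Hive-plot layout of a multilayer graph
#'
#' One radial axis per omics layer (nominal angles evenly spaced, 120
#' degrees apart for three layers); on each axis the modules are placed by
#' the rank of their anchor-trait correlation, scaled to (0, 1], ties
#' broken by module id.
#'
#' @param graph a non-empty [MultiLayerGraph-class].
#' @return data.frame with columns layer, module, angle (degrees), radius
#'   and trait_r.
#' @export
hiveLayout <- function(graph) {
  nodes <- graphNodes(graph)
  if (!nrow(nodes)) stop("the multilayer graph has no nodes")
  layers <- sort(unique(nodes$layer))   # canonical axis order
  angles <- stats::setNames((seq_along(layers) - 1) * 360 / length(layers),
                            layers)
  out <- do.call(rbind, lapply(layers, function(ly) {
    sub <- nodes[nodes$layer == ly, , drop = FALSE]
    ord <- order(sub$trait_r, sub$module)
    rk <- integer(nrow(sub)); rk[ord] <- seq_len(nrow(sub))
    data.frame(layer = ly, module = sub$module,
               angle = unname(angles[ly]), radius = rk / nrow(sub),
               trait_r = sub$trait_r, row.names = NULL)
  }))
  out
}

#' Bipartite feature network between two modules
#'
#' Correlates every feature of one module with every feature of a module
#' from another layer, 2-by-2, and links the pairs whose correlation
#' magnitude is strictly above the threshold (the displayed convention is
#' Spearman correlation > 0.35). The dense cross-correlation matrix is
#' returned alongside for the heatmap view; per-edge p and BH q values are
#' reported so users can post-filter on significance.
#'
#' @param layerA,layerB [OmicsLayer-class] objects, samples aligned.
#' @param partitionA,partitionB their [ModulePartition-class] objects.
#' @param moduleA,moduleB module ids.
#' @param method "spearman" (default, as displayed) or "pearson".
#' @param threshold correlation magnitude above which an edge is drawn.
#' @return list with \code{edges} (feature_a, feature_b, r, p, q) and
#'   \code{matrix} (the |A| x |B| cross-correlation).
#' @export
bipartiteFeatureNetwork <- function(layerA, partitionA, moduleA,
                                    layerB, partitionB, moduleB,
                                    method = c("spearman", "pearson"),
                                    threshold = 0.35) {
  method <- match.arg(method)
  fa <- partitionA@featureIDs[partitionA@labels == moduleA]
  fb <- partitionB@featureIDs[partitionB@labels == moduleB]
  if (!length(fa) || !length(fb)) stop("empty module")
  va <- layerValues(layerA)[, fa, drop = FALSE]
  vb <- layerValues(layerB)[, fb, drop = FALSE]
  stopifnot(identical(rownames(va), rownames(vb)))
  ct <- .corTestGrid(va, vb, method)
  hit <- which(!is.na(ct$r) & abs(ct$r) > threshold, arr.ind = TRUE)
  edges <- data.frame(feature_a = fa[hit[, 1]], feature_b = fb[hit[, 2]],
                      r = ct$r[hit], p = ct$p[hit], row.names = NULL)
  edges$q <- if (nrow(edges)) stats::p.adjust(edges$p, method = "BH")
             else numeric(0)
  ord <- order(-abs(edges$r))
  list(edges = edges[ord, , drop = FALSE], matrix = ct$r)
}

#' Export a multilayer or bipartite graph as GraphML
#'
#' @param x a [MultiLayerGraph-class] or a bipartite edge data.frame
#'   (columns feature_a, feature_b, r).
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportGraphML <- function(x, path) {
  if (is(x, "MultiLayerGraph")) {
    nodes <- graphNodes(x)
    edges <- graphEdges(x)
    vid <- paste(nodes$layer, nodes$module, sep = ":")
    df <- data.frame(from = paste(edges$layer_a, edges$module_a, sep = ":"),
                     to = paste(edges$layer_b, edges$module_b, sep = ":"),
                     weight = edges$r, q = edges$q)
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
      vertices = data.frame(name = vid, layer = nodes$layer,
                            module = nodes$module, trait_r = nodes$trait_r))
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = x$feature_a, to = x$feature_b, weight = x$r),
      directed = FALSE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
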